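# File input, packaged example data, and the command-line surface.

#' Read a two-way rank or score layout from delimited text
#'
#' Reads a rectangular CSV/TSV with group labels in the header and block
#' labels in the first column (or the transpose, with
#' `orientation = "groups-rows"`), validates it, and returns the matrix in
#' the canonical blocks-as-rows orientation.
#'
#' @param path File path.
#' @param delim Field delimiter, `","` by default.
#' @param orientation `"blocks-rows"` (canonical) or `"groups-rows"` if the
#'   file stores one row per group.
#' @param kind `"ranks"` (validated as within-block rankings) or `"raw"`
#'   (scores to be passed through [rank_transform()]).
#' @param allow_missing Permit empty cells (incomplete designs); otherwise a
#'   missing cell is an error naming its block and group.
#' @return Numeric matrix, blocks as rows, with dimnames, and attribute
#'   `kind`.
#' @export
read_rank_table <- function(path, delim = ",",
                            orientation = c("blocks-rows", "groups-rows"),
                            kind = c("ranks", "raw"), allow_missing = FALSE) {
  orientation <- match.arg(orientation)
  kind <- match.arg(kind)
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  if (ncol(df) < 2) stop("expected a label column plus data columns in ",
                         path, call. = FALSE)
  labels <- as.character(df[[1]])
  if (anyDuplicated(labels)) {
    stop("duplicate row labels in ", path, ": ",
         toString(labels[duplicated(labels)]), call. = FALSE)
  }
  vals <- df[-1]
  bad_col <- names(vals)[!vapply(vals, is.numeric, logical(1))]
  if (length(bad_col)) {
    stop("non-numeric cells in column(s) ", toString(bad_col), " of ", path,
         call. = FALSE)
  }
  m <- as.matrix(vals)
  rownames(m) <- labels
  if (orientation == "groups-rows") m <- t(m)
  if (anyNA(m) && !allow_missing) {
    idx <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop("missing cell at block '", rownames(m)[idx[1]], "', group '",
         colnames(m)[idx[2]], "' in ", path,
         "; read with allow_missing = TRUE and analyse as an incomplete design",
         call. = FALSE)
  }
  if (kind == "ranks" && !anyNA(m)) validate_rank_matrix(m)
  structure(m, kind = kind)
}

#' Packaged example data: qPCR method comparison
#'
#' Friedman rank sums of `k = 11` qPCR curve analysis methods over `n = 4`
#' performance indicators (bias, linearity, precision, resolution),
#' transcribed from the published comparison.  Use with
#' `pairwise_compare(qpcr_rank_sums(), n = 4)`.
#'
#' @return Named numeric vector of 11 rank sums (attribute `n` = 4 blocks).
#' @export
qpcr_rank_sums <- function() {
  df <- utils::read.csv(frsd_extdata("qpcr_rank_sums.csv"))
  rs <- stats::setNames(df$rank_sum, df$method)
  attr(rs, "n") <- 4L
  rs
}

#' Packaged example data: cell-differentiation predictive accuracy ranks
#'
#' Within-dataset ranks of `k = 12` data transformation methods on `n = 10`
#' cell differentiation datasets, transcribed from the published evaluation.
#' Two methods lack a score on dataset GDS2688 (missing by design), so that
#' block only ranks 10 methods: analyse either by excluding GDS2688
#' (complete design, `k = 12`, `n = 9`) or with all available ranks via the
#' two-part convolution (parts `(12, 9)` and `(10, 1)`).
#'
#' @return 10 x 12 numeric matrix (blocks = datasets as rows), with `NA` for
#'   the two missing cells.
#' @export
zagar_ranks <- function() {
  read_rank_table(frsd_extdata("zagar_ranks.csv"),
                  orientation = "groups-rows", allow_missing = TRUE)
}

frsd_extdata <- function(file) {
  path <- system.file("extdata", file, package = "frsd")
  if (path == "") stop("packaged data file not found: ", file, call. = FALSE)
  path
}

# ---- command-line interface -------------------------------------------------

#' Command-line interface
#'
#' Thin argument-vector interface over the package engines, used by the
#' `frsd` script in `inst/scripts`.  Subcommands: `pvalue`, `cd`, `compare`,
#' `parts`, `simulate`.  Results are printed as TSV (default) or JSON
#' (`--json`); p-values carry both full precision and 4-dp display forms,
#' and JSON additionally carries the exact numerator/denominator strings
#' where available.
#'
#' @param args Character vector of command-line arguments.
#' @return Exit status, invisibly: 0 success, 2 usage/validation error,
#'   3 domain error.
#' @examples
#' frsd_cli(c("pvalue", "--k", "5", "--n", "5", "--d", "11"))
#' @export
frsd_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0) {
    cli_usage()
    return(invisible(2L))
  }
  sub <- args[1]
  rest <- args[-1]
  handler <- switch(sub,
    pvalue = cli_pvalue, cd = cli_cd, compare = cli_compare,
    parts = cli_parts, simulate = cli_simulate,
    NULL
  )
  if (is.null(handler)) {
    message("unknown subcommand '", sub, "'")
    cli_usage()
    return(invisible(2L))
  }
  status <- tryCatch({
    handler(rest)
    0L
  },
  frsd_usage_error = function(e) {
    message(conditionMessage(e))
    2L
  },
  error = function(e) {
    message(conditionMessage(e))
    3L
  })
  invisible(status)
}

cli_usage <- function() {
  message("usage: frsd <pvalue|cd|compare|parts|simulate> [options]\n",
          "  pvalue   --k K --n N --d D [--mid] [--method exact|normal|normal-cc|range] [--json]\n",
          "  cd       --k K --n N [--alpha A] [--mode none|one-control|all-pairs]\n",
          "           [--method exact|normal|mvn|range|chisq] [--json]\n",
          "  compare  FILE [--mode all-pairs|one-control] [--control G] [--alpha A]\n",
          "           [--direction ascending|descending] [--raw] [--delim D] [--json]\n",
          "  parts    --d D --part K:N [--part K:N ...] [--adjust M] [--json]\n",
          "  simulate --k K --n N --seed S [--tie-rate R] [--json]")
}

usage_error <- function(...) {
  stop(structure(class = c("frsd_usage_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

cli_opts <- function(args, flags, switches = character()) {
  opts <- list()
  positional <- character()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (a %in% names(flags)) {
      if (i == length(args)) usage_error("missing value for ", a)
      key <- flags[[a]]
      val <- args[i + 1]
      opts[[key]] <- c(opts[[key]], val)
      i <- i + 2
    } else if (a %in% names(switches)) {
      opts[[switches[[a]]]] <- TRUE
      i <- i + 1
    } else if (startsWith(a, "--")) {
      usage_error("unknown flag '", a, "'")
    } else {
      positional <- c(positional, a)
      i <- i + 1
    }
  }
  opts$positional <- positional
  opts
}

cli_num <- function(opts, key, default = NULL) {
  if (is.null(opts[[key]])) {
    if (is.null(default)) usage_error("missing required flag --", key)
    return(default)
  }
  v <- suppressWarnings(as.numeric(opts[[key]][1]))
  if (is.na(v)) usage_error("--", key, " must be numeric")
  v
}

cli_emit <- function(x, json) {
  if (json) {
    cat(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null"), "\n")
  } else {
    df <- as.data.frame(x)
    readr::write_tsv(df, stdout())
  }
}

common_flags <- c("--k" = "k", "--n" = "n", "--d" = "d", "--alpha" = "alpha",
                  "--method" = "method", "--mode" = "mode",
                  "--control" = "control", "--direction" = "direction",
                  "--delim" = "delim", "--part" = "part", "--adjust" = "adjust",
                  "--seed" = "seed", "--tie-rate" = "tie_rate")
common_switches <- c("--json" = "json", "--mid" = "mid", "--raw" = "raw")

cli_pvalue <- function(args) {
  o <- cli_opts(args, common_flags, common_switches)
  k <- cli_num(o, "k"); n <- cli_num(o, "n"); d <- cli_num(o, "d")
  method <- if (is.null(o$method)) "exact" else o$method[1]
  rec <- switch(method,
    exact = {
      r <- exact_pvalue(d, k, n)
      p <- if (isTRUE(o$mid)) r$p_mid else if (r$ties) r$p_mid else r$p_exact
      list(d = d, k = k, n = n, method = if (isTRUE(o$mid)) "mid" else method,
           p = p, p_display = round(p, 4),
           p_num = if (isTRUE(o$mid) || r$ties) r$mid_num2 else r$p_num,
           den = if (isTRUE(o$mid) || r$ties) big_mul("2", r$den) else r$den)
    },
    normal = list(d = d, k = k, n = n, method = method,
                  p = pvalue_normal(d, k, n),
                  p_display = round(pvalue_normal(d, k, n), 4)),
    `normal-cc` = list(d = d, k = k, n = n, method = method,
                       p = pvalue_normal(d, k, n, continuity = TRUE),
                       p_display = round(pvalue_normal(d, k, n, TRUE), 4)),
    range = list(d = d, k = k, n = n, method = method,
                 p = pvalue_range(d, k, n),
                 p_display = round(pvalue_range(d, k, n), 4)),
    usage_error("unknown --method '", method, "'")
  )
  cli_emit(rec, isTRUE(o$json))
}

cli_cd <- function(args) {
  o <- cli_opts(args, common_flags, common_switches)
  k <- cli_num(o, "k"); n <- cli_num(o, "n")
  alpha <- cli_num(o, "alpha", 0.05)
  mode <- if (is.null(o$mode)) "none" else o$mode[1]
  comparisons <- switch(mode, none = "unadjusted",
                        `one-control` = "one-control",
                        `all-pairs` = "all-pairs",
                        usage_error("unknown --mode '", mode, "'"))
  if (is.null(o$method)) {
    tab <- cd_table(k, n, alpha = alpha)
    cli_emit(tab, isTRUE(o$json))
  } else {
    cd <- critical_difference(k, n, alpha, comparisons, method = o$method[1])
    cli_emit(list(k = k, n = n, alpha = alpha, mode = mode,
                  method = o$method[1], cd = cd), isTRUE(o$json))
  }
}

cli_compare <- function(args) {
  o <- cli_opts(args, common_flags, common_switches)
  if (length(o$positional) != 1) usage_error("compare needs exactly one FILE")
  delim <- if (is.null(o$delim)) "," else o$delim[1]
  kind <- if (isTRUE(o$raw)) "raw" else "ranks"
  m <- read_rank_table(o$positional, delim = delim, kind = kind)
  direction <- if (is.null(o$direction)) "ascending" else o$direction[1]
  mode <- if (is.null(o$mode)) "all-pairs" else o$mode[1]
  tab <- pairwise_compare(m, mode = mode, control = o$control,
                          alpha = cli_num(o, "alpha", 0.05),
                          ranked = !isTRUE(o$raw), direction = direction)
  cli_emit(tab, isTRUE(o$json))
}

cli_parts <- function(args) {
  o <- cli_opts(args, common_flags, common_switches)
  d <- cli_num(o, "d")
  if (is.null(o$part)) usage_error("at least one --part K:N is required")
  kn <- strsplit(o$part, ":", fixed = TRUE)
  if (any(lengths(kn) != 2)) usage_error("--part must look like K:N")
  parts <- design_parts(as.numeric(vapply(kn, `[`, "", 1)),
                        as.numeric(vapply(kn, `[`, "", 2)))
  rec <- exact_pvalue_parts(d, parts)
  m <- cli_num(o, "adjust", 1)
  out <- list(d = d, parts = paste(o$part, collapse = " "),
              p = rec$p_exact, p_adjusted = min(1, m * rec$p_exact),
              p_display = round(min(1, m * rec$p_exact), 4),
              p_num = rec$p_num, den = rec$den)
  cli_emit(out, isTRUE(o$json))
}

cli_simulate <- function(args) {
  o <- cli_opts(args, common_flags, common_switches)
  k <- cli_num(o, "k"); n <- cli_num(o, "n")
  seed <- cli_num(o, "seed")
  summ <- null_pvalue_uniformity(k, n, seed = seed,
                                 tie_rate = cli_num(o, "tie_rate", 0))
  cli_emit(summ, isTRUE(o$json))
}
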