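#' Expression table of probe intensities per condition
#'
#' @param df data.frame with a `probe` column (unique identifiers) and one
#'   column of positive normalised signal intensities per condition.
#' @param reference name of the reference (normal) condition column.
#' @return An `expression_table` (the validated data.frame with a
#'   `reference` attribute).
#' @export
expression_table <- function(df, reference) {
  stopifnot(is.data.frame(df), "probe" %in% names(df))
  conds <- setdiff(names(df), "probe")
  if (!reference %in% conds) stop("reference condition not present in table")
  if (anyDuplicated(df$probe)) stop("probe identifiers must be unique")
  vals <- as.matrix(df[, conds, drop = FALSE])
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("intensities must be positive and finite")
  }
  attr(df, "reference") <- reference
  class(df) <- c("expression_table", "data.frame")
  df
}

#' Derive a fold-change probe signature against the reference condition
#'
#' Probes with a signal two or more times higher than the reference belong to
#' the upregulated signature of that condition (ratio >= 2, boundary
#' inclusive); probes two or more times lower (ratio <= 0.5, boundary
#' inclusive, i.e. the reciprocal fold) form the downregulated signature.
#' Up and down signatures of one condition are disjoint by construction.
#'
#' @param table an [expression_table()].
#' @param condition condition column to compare against the reference.
#' @param direction `"up"` or `"down"`.
#' @param fold fold-change threshold (default 2).
#' @return A `probe_signature` list: `direction`, `probes` (character vector),
#'   `condition`, `universe_size` (total probes measured).
#' @export
derive_signature <- function(table, condition, direction = c("up", "down"),
                             fold = 2) {
  stopifnot(inherits(table, "expression_table"))
  direction <- match.arg(direction)
  reference <- attr(table, "reference")
  if (condition == reference) stop("condition must differ from the reference")
  if (!condition %in% names(table)) stop("unknown condition: ", condition)
  ref <- table[[reference]]
  if (any(ref <= 0)) stop("reference intensities must be positive")
  ratio <- table[[condition]] / ref
  keep <- if (direction == "up") ratio >= fold else ratio <= 1 / fold
  structure(list(direction = direction,
                 probes = table$probe[keep],
                 condition = condition,
                 universe_size = nrow(table)),
            class = "probe_signature")
}

#' Build the 2x2 confusion matrix of two probe signatures
#'
#' Partitions the probe universe into overlap (`a`), exclusive to A (`b`),
#' exclusive to B (`c`), and neither (`d`); `a + b + c + d` equals the
#' universe size.
#'
#' @param sigA,sigB [derive_signature()] results (or lists with a `probes`
#'   field) drawn from the same probe universe.
#' @param universe_size total number of probes measured; defaults to the
#'   signatures' recorded universe size.
#' @return A `confusion_matrix` (named integer vector `a`, `b`, `c`, `d`).
#' @export
build_confusion <- function(sigA, sigB, universe_size = NULL) {
  pA <- unique(sigA$probes)
  pB <- unique(sigB$probes)
  if (is.null(universe_size)) {
    universe_size <- sigA$universe_size
    if (!is.null(sigB$universe_size) && sigB$universe_size != universe_size) {
      stop("signatures report different universe sizes; pass universe_size")
    }
  }
  a <- length(intersect(pA, pB))
  b <- length(setdiff(pA, pB))
  c <- length(setdiff(pB, pA))
  if (a + b + c > universe_size) stop("signatures larger than the universe")
  d <- universe_size - a - b - c
  structure(c(a = a, b = b, c = c, d = as.integer(d)),
            class = "confusion_matrix")
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Computes the two-sided p-value by the point-probability
#' (minimum-likelihood) convention: with all margins fixed, p is the sum of
#' hypergeometric probabilities of every table whose point probability does
#' not exceed that of the observed table. Tables are compared on log
#' hypergeometric weights with a relative tolerance of 1e-9, which resolves
#' ties exactly for any table the weights represent exactly in double
#' precision. Degenerate margins (a zero row or column total) admit a single
#' table and return p = 1.
#'
#' The odds ratio is the sample odds ratio (a d) / (b c), flagged as `Inf`
#' when b c = 0 (and `NaN` when a d = 0 as well).
#'
#' @param m a `confusion_matrix`, a named vector with entries `a`, `b`, `c`,
#'   `d`, or a 2x2 matrix (rows = first factor, columns = second).
#' @return list with `p_value` in (0, 1] and `odds_ratio`.
#' @export
fisher_exact_two_sided <- function(m) {
  if (is.matrix(m)) {
    stopifnot(all(dim(m) == c(2, 2)))
    m <- c(a = m[1, 1], b = m[1, 2], c = m[2, 1], d = m[2, 2])
  }
  a <- m[["a"]]; b <- m[["b"]]; cc <- m[["c"]]; d <- m[["d"]]
  counts <- c(a, b, cc, d)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("confusion matrix cells must be non-negative integers")
  }
  # flagged values: Inf when only an off-diagonal cell is empty, NaN when the
  # ratio is fully degenerate (0/0)
  odds <- if (b * cc == 0) {
    if (a * d > 0) Inf else NaN
  } else {
    (a * d) / (b * cc)
  }

  m1 <- a + b          # row 1 total
  m2 <- cc + d         # row 2 total
  K <- a + cc          # column 1 total
  N <- m1 + m2
  if (m1 == 0 || m2 == 0 || K == 0 || K == N) {
    return(list(p_value = 1, odds_ratio = odds))
  }
  k <- max(0, K - m2):min(m1, K)
  lw <- lchoose(m1, k) + lchoose(m2, K - k)
  lobs <- lchoose(m1, a) + lchoose(m2, cc)
  keep <- lw <= lobs + 1e-9
  lp <- lw[keep] - lchoose(N, K)
  p <- sum(exp(lp))
  list(p_value = min(p, 1), odds_ratio = odds)
}

#' Overlap significance report for a list of signature pairs
#'
#' One row per pair: overlap count, sample odds ratio, two-sided Fisher exact
#' p-value and a significance flag at level `alpha`. No multiplicity
#' adjustment is applied.
#'
#' @param pairs named list; each element a list with components `A` and `B`,
#'   both [derive_signature()] results from the same probe universe.
#' @param universe_size total probes measured (shared universe).
#' @param alpha significance level (default 0.05).
#' @return data.frame with columns `pair`, `overlap`, `odds_ratio`, `p_value`,
#'   `significant`.
#' @export
overlap_report <- function(pairs, universe_size, alpha = 0.05) {
  stopifnot(length(pairs) >= 1)
  nm <- names(pairs)
  if (is.null(nm)) nm <- paste0("pair", seq_along(pairs))
  rows <- lapply(seq_along(pairs), function(i) {
    cm <- build_confusion(pairs[[i]]$A, pairs[[i]]$B, universe_size)
    ft <- suppressWarnings(fisher_exact_two_sided(cm))
    data.frame(pair = nm[i], overlap = cm[["a"]],
               odds_ratio = ft$odds_ratio, p_value = ft$p_value,
               significant = ft$p_value < alpha)
  })
  do.call(rbind, rows)
}

#' Read / write expression tables and signatures as delimited text
#'
#' Expression tables are CSV with a `probe` column plus one column per
#' condition; signatures are one probe identifier per line.
#'
#' @param path file path.
#' @param reference reference condition column name.
#' @return `read_expression_table` returns an [expression_table()];
#'   `write_expression_table` and `write_signature` return `path` invisibly.
#' @export
read_expression_table <- function(path, reference) {
  expression_table(utils::read.csv(path, check.names = FALSE), reference)
}

#' @rdname read_expression_table
#' @param table an [expression_table()].
#' @export
write_expression_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_expression_table
#' @param sig a `probe_signature`.
#' @export
write_signature <- function(sig, path) {
  writeLines(sig$probes, path)
  invisible(path)
}
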