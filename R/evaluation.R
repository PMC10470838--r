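#' Coefficient of variation
#'
#' Sample standard deviation (n - 1 denominator) over the mean.
#'
#' @param values numeric vector of per-sample trait values with nonzero mean.
#' @return The CV, dimensionless.
#' @export
coefficient_of_variation <- function(values) {
  values <- as.numeric(values)
  m <- mean(values)
  if (m == 0) stop("coefficient of variation undefined: zero mean")
  stats::sd(values) / m
}

#' Per-trait statistics table
#'
#' For each trait: CV on raw values, entropy divergence h = 1 - E on
#' standardized values (the same normalized-entropy code path that drives
#' the FCE-E weights), and the signed variance contribution rate from the
#' first principal component.
#'
#' @param matrix a [trait_matrix].
#' @param reference_trait trait used to orient PC1 (default: first trait).
#' @return A data frame with columns `trait`, `cv`, `h`, `var`.
#' @export
trait_stats_table <- function(matrix, reference_trait = NULL) {
  stopifnot(inherits(matrix, "trait_matrix"))
  std <- suppressWarnings(standardize(matrix))
  ed <- .entropy_divergence(std$values)
  cv <- apply(matrix$values, 2, coefficient_of_variation)
  vc <- variance_contribution(matrix, reference_trait)
  data.frame(trait = matrix$trait_names, cv = as.numeric(cv),
             h = ed$divergence, var = as.numeric(vc),
             stringsAsFactors = FALSE, row.names = NULL)
}

.pc1 <- function(matrix, reference_trait) {
  v <- matrix$values
  if (nrow(v) < 3L) stop("need at least 3 samples for PCA")
  if (is.null(reference_trait)) reference_trait <- matrix$trait_names[1L]
  j <- match(reference_trait, matrix$trait_names)
  if (is.na(j)) stop("reference trait '", reference_trait, "' not found")
  sds <- apply(v, 2, stats::sd)
  if (sds[j] == 0) stop("reference trait '", reference_trait, "' is constant")
  keep <- sds > 0
  if (any(!keep))
    warning("constant trait(s) excluded from PCA: ",
            paste(matrix$trait_names[!keep], collapse = ", "))
  vk <- v[, keep, drop = FALSE]
  z <- scale(vk)
  cm <- stats::cor(vk)
  if (anyNA(cm)) stop("degenerate covariance")
  eg <- eigen(cm, symmetric = TRUE)
  load1 <- eg$vectors[, 1L]
  scores <- as.numeric(z %*% load1)
  # orient PC1 so the composite score rises with the reference trait
  if (stats::cor(scores, v[, j]) < 0) {
    load1 <- -load1
    scores <- -scores
  }
  loadings <- rep(NA_real_, ncol(v))
  loadings[keep] <- load1
  list(loadings = loadings, scores = scores,
       explained = eg$values[1L] / sum(eg$values), kept = keep)
}

#' Signed variance contribution rate
#'
#' Each trait's PC1 loading (on z-scored traits, PC1 oriented toward the
#' reference trait) divided by the sum of PC1 loadings; the rates sum to 1
#' and a trait anti-correlated with the consensus axis gets a negative rate.
#' Constant traits cannot enter the PCA: they are excluded with a warning
#' and reported as NA.
#'
#' @param matrix a [trait_matrix] with at least 3 samples.
#' @param reference_trait trait used to orient PC1 (default: first trait).
#' @return Named numeric vector of per-trait rates summing to 1 over the
#'   non-constant traits (NA for constant traits).
#' @export
variance_contribution <- function(matrix, reference_trait = NULL) {
  stopifnot(inherits(matrix, "trait_matrix"))
  p <- .pc1(matrix, reference_trait)
  s <- sum(p$loadings[p$kept])
  if (abs(s) < 1e-9)
    stop("degenerate covariance: PC1 loadings sum to zero")
  stats::setNames(p$loadings / s, matrix$trait_names)
}

#' PCA composite-score baseline
#'
#' z-scores the traits, extracts the first principal component of their
#' correlation structure as a composite tolerance score, and ranks samples
#' by descending score (rank 1 = best). PC1's sign is fixed so the score
#' correlates positively with a named reference trait.
#'
#' @param matrix a [trait_matrix] with at least 3 samples.
#' @param reference_trait orienting trait (default: first trait).
#' @return An object of class `pca_result`: list with `sample_ids`,
#'   `pc1_scores`, `ranks` (permutation of 1..n), `explained_fraction`,
#'   `loadings`.
#' @export
pca_composite <- function(matrix, reference_trait = NULL) {
  stopifnot(inherits(matrix, "trait_matrix"))
  p <- .pc1(matrix, reference_trait)
  ranks <- integer(length(p$scores))
  ranks[order(p$scores, decreasing = TRUE)] <- seq_along(p$scores)
  structure(list(sample_ids = matrix$sample_ids,
                 pc1_scores = stats::setNames(p$scores, matrix$sample_ids),
                 ranks = stats::setNames(ranks, matrix$sample_ids),
                 explained_fraction = p$explained,
                 loadings = stats::setNames(p$loadings,
                                            matrix$trait_names)),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result> PC1 explains %.1f%% of variance\n",
              100 * x$explained_fraction))
  print(data.frame(sample_id = x$sample_ids,
                   pc1_score = round(unname(x$pc1_scores), 3),
                   rank = unname(x$ranks)), row.names = FALSE)
  invisible(x)
}

.as_grades <- function(x) {
  if (inherits(x, "fce_result"))
    return(stats::setNames(x$evaluations$grade, x$evaluations$sample_id))
  if (is.data.frame(x))
    return(stats::setNames(as.character(x$grade), x$sample_id))
  if (is.null(names(x))) stop("grades must be named by sample id")
  stats::setNames(as.character(x), names(x))
}

#' Consistency rate between two rating sets
#'
#' Fraction of samples assigned the same grade by two procedures.
#'
#' @param ratings_a,ratings_b named character vectors of grades (names =
#'   sample ids), `fce_result` objects, or data frames with `sample_id` and
#'   `grade` columns. Both must cover the same sample ids.
#' @return The agreement fraction in [0, 1].
#' @export
consistency_rate <- function(ratings_a, ratings_b) {
  a <- .as_grades(ratings_a)
  b <- .as_grades(ratings_b)
  if (!setequal(names(a), names(b)) || length(a) != length(b))
    stop("rating sets cover different sample ids")
  b <- b[names(a)]
  mean(a == b)
}

#' Rank agreement between FCE-E scores and the PCA baseline
#'
#' Spearman correlation (average ranks for ties) between the FCE-E
#' defuzzified expected scores and the PC1 composite scores, both oriented
#' so larger = more tolerant.
#'
#' @param fce an `fce_result`, or a named numeric vector of scores.
#' @param pca a `pca_result`, or a named numeric vector of scores.
#' @return Spearman correlation in [-1, 1].
#' @export
rank_agreement <- function(fce, pca) {
  a <- if (inherits(fce, "fce_result"))
    stats::setNames(fce$evaluations$expected_score,
                    fce$evaluations$sample_id) else fce
  b <- if (inherits(pca, "pca_result")) pca$pc1_scores else pca
  if (is.null(names(a)) || is.null(names(b)))
    stop("scores must be named by sample id")
  if (!setequal(names(a), names(b)))
    stop("score sets cover different sample ids")
  b <- b[names(a)]
  stats::cor(a, b, method = "spearman")
}
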