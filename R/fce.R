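#' Trait matrix
#'
#' The evaluation input: n samples x m traits plus a per-trait polarity. A
#' positive trait rises with the evaluation target (yield-referenced
#' tolerance); a negative trait falls with it and is reverse-standardized.
#'
#' @param values numeric matrix or data frame, samples in rows, traits in
#'   columns (named).
#' @param sample_ids character vector of row identifiers (defaults to row
#'   names or `S1..Sn`).
#' @param polarity character vector over traits, each `"positive"` or
#'   `"negative"`; a single value is recycled. Default all positive.
#' @return An object of class `trait_matrix` with elements `values`
#'   (numeric matrix), `sample_ids`, `trait_names`, `polarity`.
#' @export
trait_matrix <- function(values, sample_ids = NULL, polarity = "positive") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  n <- nrow(values); m <- ncol(values)
  if (n < 2L) stop("need at least 2 samples")
  if (m < 1L) stop("need at least 1 trait")
  if (anyNA(values) || !all(is.finite(values)))
    stop("trait values must be finite with no missing entries")
  if (is.null(colnames(values)))
    colnames(values) <- paste0("T", seq_len(m))
  if (is.null(sample_ids))
    sample_ids <- if (!is.null(rownames(values))) rownames(values)
                  else paste0("S", seq_len(n))
  if (length(sample_ids) != n) stop("need one sample id per row")
  polarity <- rep_len(as.character(polarity), m)
  if (!all(polarity %in% c("positive", "negative")))
    stop("polarity entries must be 'positive' or 'negative'")
  rownames(values) <- sample_ids
  structure(list(values = values, sample_ids = as.character(sample_ids),
                 trait_names = colnames(values), polarity = polarity),
            class = "trait_matrix")
}

#' @export
print.trait_matrix <- function(x, ...) {
  cat(sprintf("<trait_matrix> %d samples x %d traits (%d negative)\n",
              nrow(x$values), ncol(x$values), sum(x$polarity == "negative")))
  invisible(x)
}

#' Grade set and scores
#'
#' The ordered evaluation grades and the score attached to each; defaults
#' follow the four-grade tolerance scale scored 100/75/50/25.
#'
#' @param grades ordered labels, most tolerant first.
#' @param scores strictly decreasing numeric scores, one per grade.
#' @return An `evaluation_set` list.
#' @export
evaluation_set <- function(grades = c("Very tolerant", "Intermediate",
                                      "Susceptible", "Very susceptible"),
                           scores = c(100, 75, 50, 25)) {
  if (length(grades) != length(scores))
    stop("grades and scores must have the same length")
  if (any(diff(scores) >= 0)) stop("scores must be strictly decreasing")
  structure(list(grades = as.character(grades), scores = as.numeric(scores)),
            class = "evaluation_set")
}

#' Trapezoidal membership parameters
#'
#' Six breakpoints x1 < ... < x6 on the standardized [0, 1] scale define the
#' four trapezoids. Defaults put transition bands of full width
#' `2 * fuzzy_halfwidth` around the quartile critical values 0.25, 0.5,
#' 0.75: (0.2, 0.3, 0.45, 0.55, 0.7, 0.8).
#'
#' @param breakpoints numeric vector x1..x6, strictly increasing within
#'   [0, 1].
#' @param fuzzy_halfwidth transition half-width used to build default
#'   breakpoints when `breakpoints` is NULL (default 0.05).
#' @return A `membership_params` list with elements `breakpoints` and
#'   `fuzzy_halfwidth`.
#' @export
membership_params <- function(breakpoints = NULL, fuzzy_halfwidth = 0.05) {
  if (is.null(breakpoints)) {
    h <- fuzzy_halfwidth
    stopifnot(h > 0, h < 0.125)
    breakpoints <- c(0.25 - h, 0.25 + h, 0.5 - h, 0.5 + h, 0.75 - h, 0.75 + h)
  }
  breakpoints <- as.numeric(breakpoints)
  if (length(breakpoints) != 6L)
    stop("need exactly 6 breakpoints")
  if (breakpoints[1] < 0 || breakpoints[6] > 1 ||
      any(diff(breakpoints) <= 0))
    stop("breakpoints must be strictly increasing within [0, 1]")
  structure(list(breakpoints = breakpoints,
                 fuzzy_halfwidth = fuzzy_halfwidth),
            class = "membership_params")
}

#' Min-max standardization to [0, 1]
#'
#' Positive traits map x to (x - min)/(max - min); negative traits to
#' (max - x)/(max - min), so every output trait is positive-sense on [0, 1].
#' A constant trait cannot be scaled: it is set to 0.5 everywhere with a
#' warning, and the entropy weighting downstream assigns it weight zero.
#'
#' @param matrix a [trait_matrix].
#' @return A standardized [trait_matrix] (all polarities positive) with
#'   attribute `constant_traits` naming any constant columns.
#' @export
standardize <- function(matrix) {
  stopifnot(inherits(matrix, "trait_matrix"))
  v <- matrix$values
  const <- character()
  for (j in seq_len(ncol(v))) {
    rng <- range(v[, j])
    if (rng[1] == rng[2]) {
      const <- c(const, matrix$trait_names[j])
      v[, j] <- 0.5
    } else if (matrix$polarity[j] == "positive") {
      v[, j] <- (v[, j] - rng[1]) / (rng[2] - rng[1])
    } else {
      v[, j] <- (rng[2] - v[, j]) / (rng[2] - rng[1])
    }
  }
  if (length(const))
    warning("constant trait(s) standardized to 0.5 and given zero weight: ",
            paste(const, collapse = ", "))
  out <- trait_matrix(v, matrix$sample_ids, "positive")
  attr(out, "constant_traits") <- const
  out
}

# Normalized Shannon entropy and divergence of each standardized trait.
# Shares p_ij = x_ij / sum_i(x_ij); E_j = -sum(p log2 p)/log2(n) in [0, 1];
# divergence d_j = 1 - E_j. Shared by entropy_weights() and
# trait_stats_table().
.entropy_divergence <- function(values) {
  n <- nrow(values)
  cs <- colSums(values)
  E <- vapply(seq_len(ncol(values)), function(j) {
    if (cs[j] <= 0) return(1)  # all-zero column carries no information
    p <- values[, j] / cs[j]
    p <- p[p > 0]
    -sum(p * log2(p)) / log2(n)
  }, numeric(1))
  E <- pmin(pmax(E, 0), 1)
  list(entropy = E, divergence = 1 - E)
}

#' Entropy weights of the evaluation index system
#'
#' Each standardized trait's values are turned into shares
#' p_ij = x_ij / sum_i x_ij, the Shannon entropy
#' E_j = -(1/log2 n) * sum_i p_ij log2 p_ij measures how evenly the trait is
#' spread across samples, and the weight is the normalized divergence
#' w_j = (1 - E_j) / sum_k (1 - E_k). Traits that barely vary carry little
#' information and get near-zero weight.
#'
#' @param standardized a standardized [trait_matrix] (see [standardize()]).
#' @return An object of class `weight_vector`: list with `weights`,
#'   `divergences`, `entropies` (all named by trait) and `trait_names`.
#' @export
entropy_weights <- function(standardized) {
  stopifnot(inherits(standardized, "trait_matrix"))
  v <- standardized$values
  if (any(v < -1e-9) || any(v > 1 + 1e-9))
    stop("entropy_weights expects a standardized matrix on [0, 1]")
  ed <- .entropy_divergence(v)
  d <- ed$divergence
  if (sum(d) <= 1e-12)
    stop("no discriminating information: every trait has maximal entropy")
  w <- d / sum(d)
  names(w) <- names(d) <- names(ed$entropy) <- standardized$trait_names
  structure(list(weights = w, divergences = d, entropies = ed$entropy,
                 trait_names = standardized$trait_names),
            class = "weight_vector")
}

#' @export
print.weight_vector <- function(x, ...) {
  cat("<weight_vector>\n")
  print(round(rbind(weight = x$weights, divergence = x$divergences), 4))
  invisible(x)
}

#' Trapezoidal grade memberships of a standardized value
#'
#' Maps a standardized, positive-sense value to its membership in the four
#' grades (most tolerant first). The four piecewise-linear functions are
#' complementary, so the memberships sum to 1 for any x in [0, 1]; values
#' outside [0, 1] are clamped.
#'
#' @param x numeric vector of standardized values.
#' @param params a [membership_params()].
#' @return A length(x) x 4 matrix of memberships, columns in grade order.
#' @export
#' @examples
#' grade_membership(c(0, 0.5, 0.75, 0.9))
grade_membership <- function(x, params = membership_params()) {
  stopifnot(inherits(params, "membership_params"))
  b <- params$breakpoints
  x <- pmin(pmax(as.numeric(x), 0), 1)
  x1 <- b[1]; x2 <- b[2]; x3 <- b[3]; x4 <- b[4]; x5 <- b[5]; x6 <- b[6]
  v1 <- ifelse(x < x5, 0, ifelse(x <= x6, (x - x5) / (x6 - x5), 1))
  v2 <- ifelse(x < x3, 0,
        ifelse(x < x4, (x - x3) / (x4 - x3),
        ifelse(x < x5, 1,
        ifelse(x < x6, (x6 - x) / (x6 - x5), 0))))
  v3 <- ifelse(x < x1, 0,
        ifelse(x < x2, (x - x1) / (x2 - x1),
        ifelse(x < x3, 1,
        ifelse(x < x4, (x4 - x) / (x4 - x3), 0))))
  v4 <- ifelse(x < x1, 1, ifelse(x <= x2, (x2 - x) / (x2 - x1), 0))
  out <- cbind(v1, v2, v3, v4)
  dimnames(out) <- NULL
  out
}

#' Per-sample fuzzy evaluation matrix
#'
#' Row j of the result is the grade membership vector of trait j's
#' standardized value.
#'
#' @param sample_row named numeric vector of a sample's standardized trait
#'   values.
#' @param params a [membership_params()].
#' @return An m x 4 membership matrix (rows named by trait).
#' @export
fuzzy_matrix <- function(sample_row, params = membership_params()) {
  r <- grade_membership(sample_row, params)
  rownames(r) <- names(sample_row)
  r
}

#' Weighted-average fuzzy composition
#'
#' Composes trait weights with the membership matrix using the
#' multiplication-addition operator: b_k = sum_j w_j * r_jk. With weights
#' and membership rows each summing to 1, b sums to 1.
#'
#' @param weights a `weight_vector` or a numeric weight vector summing to 1.
#' @param r an m x 4 membership matrix.
#' @return The composed 4-vector b.
#' @export
fuzzy_compose <- function(weights, r) {
  w <- if (inherits(weights, "weight_vector")) weights$weights else weights
  if (!is.matrix(r)) stop("`r` must be a matrix")
  if (length(w) != nrow(r))
    stop("dimension mismatch: ", length(w), " weights vs ", nrow(r),
         " membership rows")
  as.numeric(w %*% r)
}

#' Maximum-membership rating
#'
#' Assigns the grade with the largest composed membership. Ties go to the
#' more tolerant grade and are flagged.
#'
#' @param b composed membership 4-vector (sums to 1).
#' @param eset an [evaluation_set()].
#' @return List with `grade`, `score`, `tie` (logical).
#' @export
fce_rate <- function(b, eset = evaluation_set()) {
  stopifnot(inherits(eset, "evaluation_set"))
  if (length(b) != length(eset$grades))
    stop("b must have one entry per grade")
  k <- which.max(b)  # first maximum = more tolerant grade
  list(grade = eset$grades[k], score = eset$scores[k],
       tie = sum(b == max(b)) > 1L)
}

#' Entropy-weighted fuzzy comprehensive evaluation (FCE-E)
#'
#' The full grading algorithm: min-max standardize the trait matrix,
#' compute entropy weights, build each sample's trapezoidal membership
#' matrix, compose it with the weights, and rate by maximum membership.
#' The defuzzified expected score sum_k b_k * score_k is also reported as a
#' continuous tolerance score.
#'
#' @param matrix a [trait_matrix].
#' @param params a [membership_params()].
#' @param eset an [evaluation_set()].
#' @return An object of class `fce_result`: list with
#'   `evaluations` (data frame: sample_id, b1..b4, grade, score, tie,
#'   expected_score), `r` (per-sample membership matrices), `weights`
#'   (the `weight_vector`), `params`, `eset`.
#' @export
#' @examples
#' tm <- trait_matrix(cbind(height = c(10, 20, 30), wilt = c(5, 3, 1)),
#'                    polarity = c("positive", "negative"))
#' fce_evaluate(tm)$evaluations
fce_evaluate <- function(matrix, params = membership_params(),
                         eset = evaluation_set()) {
  stopifnot(inherits(matrix, "trait_matrix"))
  std <- standardize(matrix)
  wv <- entropy_weights(std)
  n <- nrow(std$values)
  rs <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    r <- fuzzy_matrix(std$values[i, ], params)
    b <- fuzzy_compose(wv, r)
    rating <- fce_rate(b, eset)
    rs[[i]] <- r
    bcols <- as.data.frame(as.list(stats::setNames(
      b, paste0("b", seq_along(b)))))
    rows[[i]] <- cbind(data.frame(sample_id = std$sample_ids[i],
                                  stringsAsFactors = FALSE),
                       bcols,
                       data.frame(grade = rating$grade,
                                  score = rating$score,
                                  tie = rating$tie,
                                  expected_score = sum(b * eset$scores),
                                  stringsAsFactors = FALSE))
  }
  names(rs) <- std$sample_ids
  structure(list(evaluations = do.call(rbind, rows), r = rs, weights = wv,
                 params = params, eset = eset),
            class = "fce_result")
}

#' @export
print.fce_result <- function(x, ...) {
  cat("<fce_result>\n")
  print(x$evaluations[, c("sample_id", "grade", "score", "expected_score")],
        row.names = FALSE)
  invisible(x)
}
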