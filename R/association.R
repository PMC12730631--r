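# Interspecific association statistics on presence/absence data:
# - overall association via the variance-ratio (VR) test: the variance of
#   per-site richness relative to the sum of per-species binomial
#   variances; VR = 1 under independence, > 1 overall positive, < 1
#   overall negative; W = N * VR is referred to chi-square bounds with N
#   degrees of freedom.
# - pairwise association via the point (phi) correlation coefficient on
#   2x2 co-occurrence tables, with a chi-square significance class per
#   pair, a stability verdict from the positive/negative pair balance,
#   and network edge-list export.

#' Binarise an abundance matrix to presence/absence
#'
#' @param mat entity x site nonnegative numeric matrix.
#' @param threshold presence cutoff: entry is present iff abundance is
#'   strictly greater (default 0).
#' @return Object of class `presence_matrix`: 0/1 matrix with the same
#'   dimnames.
#' @export
presence_absence <- function(mat, threshold = 0) {
  stopifnot(is.matrix(mat), is.numeric(mat))
  if (any(mat < 0)) stop("abundances must be >= 0")
  if (nrow(mat) < 2) stop("need at least 2 entities")
  if (ncol(mat) < 2) stop("need at least 2 sites")
  pm <- (mat > threshold) * 1L
  class(pm) <- c("presence_matrix", class(pm))
  pm
}

as_presence <- function(pm) {
  if (!inherits(pm, "presence_matrix")) {
    stopifnot(is.matrix(pm))
    if (!all(pm %in% c(0, 1))) stop("matrix is not binary")
  }
  unclass(pm)
}

#' Overall interspecific association (variance-ratio test)
#'
#' With `p_i` the occupancy of entity `i` over `N` sites and `T_j` the
#' entity richness of site `j`:
#' `sigma_T^2 = sum(p_i (1 - p_i))` (expected richness variance under
#' independence), `S_T^2 = mean((T_j - mean(T))^2)` (observed richness
#' variance), `VR = S_T^2 / sigma_T^2` and `W = N * VR`. VR > 1 indicates
#' overall positive association, VR < 1 negative, VR = 1 none. W is
#' referred to a chi-square distribution with N degrees of freedom;
#' the association is significant at level `alpha` when W falls outside
#' the central `1 - alpha` region, i.e. below the `alpha/2` or above the
#' `1 - alpha/2` quantile. (Published uses of this test often quote the
#' 5th/95th percentile bounds while calling the level 0.05; that pair of
#' bounds is a 10% two-sided test and is reproduced here by `alpha = 0.1`.)
#'
#' @param pm a `presence_matrix` (or binary matrix), entities x sites.
#' @param alpha total two-sided significance level (default 0.05).
#' @return Object of class `overall_association`: list with `sigma_T2`,
#'   `S_T2`, `VR`, `W`, `N`, `S`, `verdict` (`"positive"`, `"negative"`,
#'   `"none"`), `significant`, `chi2_lower`, `chi2_upper`, `alpha`.
#' @export
overall_variance_ratio <- function(pm, alpha = 0.05) {
  m <- as_presence(pm)
  stopifnot(alpha > 0, alpha < 1)
  N <- ncol(m)
  S <- nrow(m)
  p_i <- rowMeans(m)
  sigma_T2 <- sum(p_i * (1 - p_i))
  if (sigma_T2 == 0)
    stop("variance ratio undefined: every entity is ubiquitous or absent")
  T_j <- colSums(m)
  S_T2 <- mean((T_j - mean(T_j))^2)
  VR <- S_T2 / sigma_T2
  W <- N * VR
  lo <- stats::qchisq(alpha / 2, df = N)
  hi <- stats::qchisq(1 - alpha / 2, df = N)
  structure(
    list(sigma_T2 = sigma_T2, S_T2 = S_T2, VR = VR, W = W, N = N, S = S,
         verdict = if (VR > 1) "positive" else if (VR < 1) "negative"
                   else "none",
         significant = (W < lo || W > hi),
         chi2_lower = lo, chi2_upper = hi, alpha = alpha),
    class = "overall_association")
}

#' @export
print.overall_association <- function(x, ...) {
  cat("<overall_association> VR = ", format(x$VR, digits = 4),
      " (W = ", format(x$W, digits = 4), ", N = ", x$N, ")\n", sep = "")
  cat("  verdict: ", x$verdict,
      if (x$significant) " (significant, " else " (not significant, ",
      "alpha = ", x$alpha, ")\n", sep = "")
  invisible(x)
}

#' 2x2 co-occurrence table for an entity pair
#'
#' Standard convention over `N` sites: `a` = both present, `b` = only the
#' first present, `c` = only the second present, `d` = neither.
#'
#' @param pm a `presence_matrix` (or binary matrix).
#' @param i,k entity names or row indices.
#' @return named integer vector `c(a, b, c, d)` with `a+b+c+d = N`.
#' @export
contingency_2x2 <- function(pm, i, k) {
  m <- as_presence(pm)
  x <- m[i, ]
  y <- m[k, ]
  c(a = sum(x == 1 & y == 1), b = sum(x == 1 & y == 0),
    c = sum(x == 0 & y == 1), d = sum(x == 0 & y == 0))
}

#' Point (phi) correlation coefficient
#'
#' `phi = (ad - bc) / sqrt((a+b)(a+c)(b+d)(c+d))`, the Pearson correlation
#' of the two binary presence vectors, in `[-1, 1]`. Undefined (`NA`,
#' never +/-Inf) when any marginal of the 2x2 table is zero, i.e. when one
#' pattern is constant.
#'
#' @param a,b,c,d 2x2 co-occurrence counts (see [contingency_2x2()]); `a`
#'   may also be the 4-vector.
#' @return phi, or `NA` when undefined.
#' @export
point_correlation <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.null(b)) { stopifnot(length(a) == 4); b <- a[2]; c <- a[3]; d <- a[4]; a <- a[1] }
  if (a + b + c + d < 2) stop("need at least 2 sites")
  denom <- (a + b) * (a + c) * (b + d) * (c + d)
  if (denom == 0) return(NA_real_)
  unname((a * d - b * c) / sqrt(denom))
}

#' Pairwise phi association with significance classes
#'
#' For every unordered entity pair: the 2x2 table, phi, the chi-square
#' statistic `N * phi^2` (1 df), and a class:
#' `sig_positive` / `sig_negative` when `N * phi^2` exceeds the
#' chi-square critical value at `alpha` (1 df), signed by phi; otherwise
#' `positive` / `negative` by the sign of phi (phi = 0 counts as positive
#' by convention and is flagged in `zero_phi`); `undefined` when phi is
#' undefined (a constant pattern).
#'
#' @param pm a `presence_matrix` (or binary matrix).
#' @param alpha pairwise significance level (default 0.05).
#' @return data.frame of class `pair_association`: `entity_a`, `entity_b`,
#'   `a`, `b`, `c`, `d`, `phi`, `chi2`, `class`, `zero_phi`.
#' @export
classify_pairs <- function(pm, alpha = 0.05) {
  m <- as_presence(pm)
  if (nrow(m) < 2) stop("need at least 2 entities")
  N <- ncol(m)
  crit <- stats::qchisq(1 - alpha, df = 1)
  ids <- rownames(m) %||% as.character(seq_len(nrow(m)))
  pairs <- utils::combn(seq_len(nrow(m)), 2)
  res <- apply(pairs, 2, function(ik) {
    tab <- contingency_2x2(m, ik[1], ik[2])
    phi <- point_correlation(tab)
    chi2 <- if (is.na(phi)) NA_real_ else N * phi^2
    cls <- if (is.na(phi)) "undefined"
      else if (chi2 > crit && phi > 0) "sig_positive"
      else if (chi2 > crit && phi < 0) "sig_negative"
      else if (phi >= 0) "positive" else "negative"
    data.frame(entity_a = ids[ik[1]], entity_b = ids[ik[2]],
               a = tab[["a"]], b = tab[["b"]], c = tab[["c"]], d = tab[["d"]],
               phi = phi, chi2 = chi2, class = cls,
               zero_phi = !is.na(phi) && phi == 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "N") <- N
  attr(out, "alpha") <- alpha
  class(out) <- c("pair_association", "data.frame")
  out
}

#' Community stability verdict from pair associations
#'
#' Counts positively and negatively associated pairs (significant classes
#' included in their sign). When positive pairs outnumber negative pairs
#' the community tends to be stable; when they are outnumbered it is read
#' as being in succession.
#'
#' @param pairs a `pair_association` data.frame from [classify_pairs()].
#' @return list: `n_positive`, `n_negative`, `n_sig_positive`,
#'   `n_sig_negative`, `n_undefined`, `ratio` (positive/negative, `Inf`
#'   when no negative pairs), `verdict` (`"stable"`, `"successional"`, or
#'   `"indeterminate"` on a tie).
#' @export
stability_summary <- function(pairs) {
  stopifnot(is.data.frame(pairs), "class" %in% names(pairs))
  cls <- pairs$class
  n_pos <- sum(cls %in% c("positive", "sig_positive"))
  n_neg <- sum(cls %in% c("negative", "sig_negative"))
  list(n_positive = n_pos, n_negative = n_neg,
       n_sig_positive = sum(cls == "sig_positive"),
       n_sig_negative = sum(cls == "sig_negative"),
       n_undefined = sum(cls == "undefined"),
       ratio = if (n_neg == 0) Inf else n_pos / n_neg,
       verdict = if (n_pos > n_neg) "stable"
                 else if (n_pos < n_neg) "successional" else "indeterminate")
}

#' Pairwise Pearson correlation summary
#'
#' Pearson r between entity abundance vectors, by default on
#' `log10(x + 1)`-transformed values (the standard normalising transform
#' for skewed plankton abundances). Reports counts of positive and
#' negative pairs and of strong pairs with `r > strong_r`. Zero-variance
#' entities cannot be correlated; their pairs are skipped and flagged.
#'
#' @param mat entity x sample numeric matrix with at least 3 samples.
#' @param strong_r strong-correlation cutoff (strict; default 0.7).
#' @param log_transform apply `log10(x + 1)` first (default `TRUE`).
#' @return list: `pairs` (data.frame `entity_a`, `entity_b`, `r`, `strong`),
#'   `n_positive`, `n_negative`, `n_strong`, `skipped` (entities with zero
#'   variance).
#' @export
pearson_pair_summary <- function(mat, strong_r = 0.7, log_transform = TRUE) {
  stopifnot(is.matrix(mat), is.numeric(mat))
  if (ncol(mat) < 3) stop("need at least 3 samples per entity")
  x <- if (log_transform) log10(mat + 1) else mat
  vars <- apply(x, 1, stats::var)
  skipped <- rownames(x)[vars == 0]
  keep <- vars > 0
  x <- x[keep, , drop = FALSE]
  if (nrow(x) < 2)
    return(list(pairs = data.frame(entity_a = character(), entity_b = character(),
                                   r = numeric(), strong = logical()),
                n_positive = 0L, n_negative = 0L, n_strong = 0L,
                skipped = skipped))
  cm <- stats::cor(t(x))
  idx <- which(upper.tri(cm), arr.ind = TRUE)
  pairs <- data.frame(entity_a = rownames(cm)[idx[, 1]],
                      entity_b = colnames(cm)[idx[, 2]],
                      r = cm[idx], stringsAsFactors = FALSE)
  pairs$strong <- pairs$r > strong_r
  list(pairs = pairs,
       n_positive = sum(pairs$r > 0),
       n_negative = sum(pairs$r < 0),
       n_strong = sum(pairs$strong),
       skipped = skipped)
}

#' Export a pair-association network edge list
#'
#' Writes a TSV edge list `(entity_a, entity_b, phi, chi2, class)`
#' excluding undefined pairs; the file re-reads losslessly at stored
#' precision via [read_results()].
#'
#' @param pairs a `pair_association` data.frame from [classify_pairs()].
#' @param path output file path.
#' @param digits significant digits for phi and chi2.
#' @export
export_network <- function(pairs, path, digits = 6) {
  stopifnot(is.data.frame(pairs))
  edges <- pairs[pairs$class != "undefined",
                 c("entity_a", "entity_b", "phi", "chi2", "class"),
                 drop = FALSE]
  write_results(edges, path, format = "delimited", digits = digits)
}
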