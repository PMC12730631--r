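# Levins' niche breadth and pairwise niche overlap over resource states.
# Resource states are sampling units (site x season "quadrats"); entities
# are functional groups by default, species optionally. Overlap uses the
# proportional-similarity (Schoener) form 1 - 0.5 * sum|p_i - p_k| as the
# default; the classic Pianka product-moment form is available behind an
# option for comparison. Both operate on normalised use profiles.

#' Resource-use profiles
#'
#' Normalises each entity row of an entity x sample matrix to a
#' proportional-use profile `P_ij = x_ij / sum_j(x_ij)`. Entities with zero
#' total are excluded with a warning (their profile is undefined).
#'
#' @param mat entity x sample nonnegative numeric matrix.
#' @return entity x sample matrix of profiles, rows summing to 1.
#' @export
niche_profiles <- function(mat) {
  stopifnot(is.matrix(mat), is.numeric(mat))
  if (any(mat < 0)) stop("abundances must be >= 0")
  totals <- rowSums(mat)
  if (all(totals == 0)) stop("no entity with positive total abundance")
  if (any(totals == 0)) {
    warning("excluding zero-total entities: ",
            paste(rownames(mat)[totals == 0], collapse = ", "))
    mat <- mat[totals > 0, , drop = FALSE]
    totals <- totals[totals > 0]
  }
  sweep(mat, 1, totals, "/")
}

#' Levins' niche breadth
#'
#' `B_i = 1 / sum_j(P_ij^2)`: 1 for a specialist using a single state, `r`
#' for a generalist spread uniformly over `r` states.
#'
#' @param p proportional-use profile (nonnegative, summing to 1 within
#'   1e-9), or a profile matrix (rows = entities).
#' @return breadth value(s) in `[1, r]`.
#' @export
levins_breadth <- function(p) {
  if (is.matrix(p)) return(apply(p, 1, levins_breadth))
  check_proportions(p)
  1 / sum(p^2)
}

#' Niche overlap between two use profiles
#'
#' Default `"schoener"` is the proportional-similarity form
#' `O_ik = 1 - 0.5 * sum_j |P_ij - P_kj|`; `"pianka"` is the symmetric
#' product-moment form `sum(P_ij P_kj) / sqrt(sum(P_ij^2) sum(P_kj^2))`.
#' Both are 1 for identical profiles and 0 for disjoint supports.
#'
#' @param p_i,p_k proportional-use profiles over the same ordered states.
#' @param method `"schoener"` (default) or `"pianka"`.
#' @return overlap in `[0, 1]`.
#' @export
niche_overlap <- function(p_i, p_k, method = c("schoener", "pianka")) {
  method <- match.arg(method)
  if (length(p_i) != length(p_k))
    stop("profiles must cover the same resource states")
  check_proportions(p_i)
  check_proportions(p_k)
  switch(method,
         schoener = 1 - 0.5 * sum(abs(p_i - p_k)),
         pianka = sum(p_i * p_k) / sqrt(sum(p_i^2) * sum(p_k^2)))
}

#' Niche breadth, overlap matrix and high-overlap pairs
#'
#' Full niche analysis of an entity x sample matrix: profiles, Levins'
#' breadth per entity, the symmetric overlap matrix (unit diagonal), and
#' the list of pairs exceeding the overlap threshold.
#'
#' @param mat entity x sample nonnegative matrix (zero-total entities are
#'   dropped with a warning).
#' @param threshold high-overlap cutoff (strict; default 0.7).
#' @param method overlap form, see [niche_overlap()].
#' @return Object of class `niche_result`: list with `breadth` (named
#'   vector), `overlap` (matrix), `high_pairs` (data.frame `entity_a`,
#'   `entity_b`, `overlap`, sorted decreasing), `threshold`, `method`.
#' @export
niche_analysis <- function(mat, threshold = 0.7,
                           method = c("schoener", "pianka")) {
  method <- match.arg(method)
  prof <- niche_profiles(mat)
  n <- nrow(prof)
  ov <- matrix(1, n, n, dimnames = list(rownames(prof), rownames(prof)))
  if (n > 1) {
    for (i in seq_len(n - 1)) for (k in (i + 1):n) {
      ov[i, k] <- ov[k, i] <- niche_overlap(prof[i, ], prof[k, ], method)
    }
  }
  res <- structure(
    list(breadth = levins_breadth(prof), overlap = ov,
         profiles = prof, threshold = threshold, method = method),
    class = "niche_result")
  res$high_pairs <- high_overlap_pairs(res, threshold)
  res
}

#' Extract high-overlap pairs
#'
#' Unordered entity pairs with overlap strictly above the threshold,
#' sorted by decreasing overlap.
#'
#' @param result a `niche_result` from [niche_analysis()], or a symmetric
#'   overlap matrix.
#' @param threshold cutoff (strict; default 0.7).
#' @return data.frame `entity_a`, `entity_b`, `overlap`.
#' @export
high_overlap_pairs <- function(result, threshold = 0.7) {
  ov <- if (inherits(result, "niche_result")) result$overlap else result
  stopifnot(is.matrix(ov), nrow(ov) == ncol(ov))
  ids <- rownames(ov) %||% as.character(seq_len(nrow(ov)))
  idx <- which(upper.tri(ov) & ov > threshold, arr.ind = TRUE)
  out <- data.frame(entity_a = ids[idx[, 1]],
                    entity_b = ids[idx[, 2]],
                    overlap = ov[idx],
                    stringsAsFactors = FALSE)
  out[order(-out$overlap, out$entity_a, out$entity_b), , drop = FALSE]
}

#' @export
print.niche_result <- function(x, ...) {
  cat("<niche_result> ", length(x$breadth), " entities, overlap method '",
      x$method, "'\n", sep = "")
  cat("  breadth range: [", format(min(x$breadth), digits = 4), ", ",
      format(max(x$breadth), digits = 4), "]\n", sep = "")
  cat("  high-overlap pairs (>", x$threshold, "): ",
      nrow(x$high_pairs), "\n", sep = "")
  invisible(x)
}
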