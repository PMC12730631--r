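# Alpha diversity, dominance, composition percentages and Bray-Curtis
# similarity. All logarithms are base 2, matching the classical marine-survey
# formulation (H' in bits; Margalef and Pielou share the same base).

check_proportions <- function(p, tol = 1e-9) {
  if (any(p < 0)) stop("proportions must be >= 0")
  if (abs(sum(p) - 1) > tol)
    stop("proportions must sum to 1 (got ", format(sum(p)), ")")
  p
}

#' Shannon-Wiener diversity H' (bits)
#'
#' `H' = -sum(p_i * log2(p_i))` over nonzero proportions.
#'
#' @param p numeric vector of abundance proportions (>= 0, summing to 1
#'   within 1e-9; zeros are skipped).
#' @return H' in bits; 0 for a single-species community.
#' @export
shannon_index <- function(p) {
  p <- check_proportions(p)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Margalef richness d
#'
#' `d = (S - 1) / log2(N)` where `S` is the species count and `N` the total
#' number of individuals in the unit. By convention `d = 0` when `S = 1`;
#' `N <= 1` with `S > 1` leaves the index undefined (`NA`).
#'
#' @param S species count (>= 1).
#' @param N total individuals (or total abundance) in the unit.
#' @return d, or `NA` when undefined.
#' @export
margalef_index <- function(S, N) {
  stopifnot(S >= 1)
  if (S == 1) return(0)
  if (N <= 1) return(NA_real_)
  (S - 1) / log2(N)
}

#' Pielou evenness J'
#'
#' `J' = H' / log2(S)`; undefined (`NA`, not 0) for a single-species unit.
#'
#' @param H_prime Shannon-Wiener index in bits.
#' @param S species count (>= 1).
#' @return J' in `[0, 1]`, or `NA` when `S = 1`.
#' @export
pielou_index <- function(H_prime, S) {
  stopifnot(S >= 1)
  if (S == 1) return(NA_real_)
  H_prime / log2(S)
}

#' Simpson diversity D
#'
#' `D = 1 - sum(p_i^2)`.
#'
#' @inheritParams shannon_index
#' @return D in `[0, 1)`.
#' @export
simpson_index <- function(p) {
  p <- check_proportions(p)
  1 - sum(p^2)
}

#' Per-unit diversity table
#'
#' Computes S, N, H', d, J' and D per sample or pooled per stratum x season.
#' Proportions are taken on volume-normalised abundance by default so
#' unequal filtered volumes are handled; `use = "counts"` switches to raw
#' individual counts.
#'
#' @param ds a [community_dataset()].
#' @param by `"sample"` (default) or `"stratum_season"`.
#' @param use `"abundance"` (default) or `"counts"`.
#' @return data.frame with one row per unit: `unit`, `S`, `N`, `H_prime`,
#'   `d_margalef`, `J_prime`, `D_simpson`.
#' @export
diversity_table <- function(ds, by = c("sample", "stratum_season"),
                            use = c("abundance", "counts")) {
  stopifnot(inherits(ds, "community_dataset"))
  by <- match.arg(by)
  use <- match.arg(use)
  mat <- abundance_matrix(ds, measure = if (use == "counts") "counts"
                                        else "abundance")
  if (by == "stratum_season") {
    idx <- match(colnames(mat), ds$samples$sample_id)
    unit <- paste(ds$samples$stratum[idx], ds$samples$season[idx], sep = ":")
    units <- unique(unit)
    mat <- vapply(units, function(u)
      rowSums(mat[, unit == u, drop = FALSE]), numeric(nrow(mat)))
    mat <- matrix(mat, ncol = length(units),
                  dimnames = list(ds$species, units))
  }
  res <- lapply(colnames(mat), function(u) {
    x <- mat[, u]
    x <- x[x > 0]
    S <- length(x)
    N <- sum(x)
    if (S == 0)
      return(data.frame(unit = u, S = 0L, N = 0, H_prime = NA_real_,
                        d_margalef = NA_real_, J_prime = NA_real_,
                        D_simpson = NA_real_))
    p <- x / N
    H <- shannon_index(p)
    data.frame(unit = u, S = S, N = N, H_prime = H,
               d_margalef = margalef_index(S, N),
               J_prime = pielou_index(H, S),
               D_simpson = simpson_index(p),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Dominance index Y
#'
#' For each species over a scope of samples: `Y = (n_i / N) * f_i`, where
#' `n_i / N` is the species' share of the pooled abundance and `f_i` the
#' fraction of scope samples where it occurs. A species is dominant when
#' `Y > 0.02` (strictly; a tie at exactly 0.02 is not dominant).
#'
#' @param ds a [community_dataset()].
#' @param samples optional character vector restricting the scope (default:
#'   all samples).
#' @param threshold dominance cutoff on Y (default 0.02).
#' @param use `"abundance"` (default, volume-normalised) or `"counts"`.
#' @return data.frame sorted by decreasing Y: `species_id`, `n_share`,
#'   `f_occurrence`, `Y`, `is_dominant`.
#' @export
dominance <- function(ds, samples = NULL, threshold = 0.02,
                      use = c("abundance", "counts")) {
  stopifnot(inherits(ds, "community_dataset"))
  use <- match.arg(use)
  mat <- abundance_matrix(ds, measure = if (use == "counts") "counts"
                                        else "abundance")
  if (!is.null(samples)) {
    missing_s <- setdiff(samples, colnames(mat))
    if (length(missing_s) > 0)
      stop("unknown sample(s): ", paste(missing_s, collapse = ", "))
    mat <- mat[, samples, drop = FALSE]
  }
  total <- sum(mat)
  if (total == 0) stop("dominance undefined: all-zero scope")
  n_share <- rowSums(mat) / total
  f_occ <- rowMeans(mat > 0)
  Y <- n_share * f_occ
  out <- data.frame(species_id = rownames(mat), n_share = n_share,
                    f_occurrence = f_occ, Y = Y,
                    is_dominant = Y > threshold,
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(-out$Y, out$species_id), , drop = FALSE]
}

#' Species-composition percentages by class
#'
#' Share of each taxonomic class in the species inventory, e.g. 19 rotifer
#' species out of 69 collected -> 27.54%.
#'
#' @param counts named numeric vector of per-class species counts (>= 0,
#'   positive total).
#' @return data.frame with `class`, `count`, `fraction` and `percent`
#'   (the fraction rendered at 2 decimals, as reported in survey tables).
#' @export
composition_percentages <- function(counts) {
  if (is.null(names(counts)) || any(!nzchar(names(counts))))
    stop("counts must be a named vector of per-class species counts")
  if (any(counts < 0)) stop("counts must be >= 0")
  total <- sum(counts)
  if (total == 0) stop("composition undefined: zero total")
  frac <- counts / total
  data.frame(class = names(counts), count = as.numeric(counts),
             fraction = as.numeric(frac),
             percent = round(100 * as.numeric(frac), 2),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Bray-Curtis similarity
#'
#' `1 - sum(|x_i - y_i|) / sum(x_i + y_i)`: 1 for identical nonzero
#' profiles, 0 for disjoint supports. Undefined (`NA`) when both vectors
#' are all zero.
#'
#' @param x,y nonnegative numeric vectors of equal length.
#' @return similarity in `[0, 1]`, or `NA`.
#' @export
bray_curtis <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (any(x < 0) || any(y < 0)) stop("abundances must be >= 0")
  denom <- sum(x + y)
  if (denom == 0) return(NA_real_)
  1 - sum(abs(x - y)) / denom
}

#' Pairwise Bray-Curtis similarity matrix
#'
#' @param mat entity x unit numeric matrix; similarity is computed between
#'   unit columns.
#' @return symmetric unit x unit similarity matrix.
#' @export
bray_curtis_matrix <- function(mat) {
  stopifnot(is.matrix(mat))
  n <- ncol(mat)
  out <- matrix(NA_real_, n, n, dimnames = list(colnames(mat), colnames(mat)))
  for (i in seq_len(n)) for (j in seq_len(i)) {
    out[i, j] <- out[j, i] <- bray_curtis(mat[, i], mat[, j])
  }
  out
}
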