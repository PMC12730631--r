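test_that("diversity indices match their closed forms", {
  # Shannon-Wiener (bits)
  expect_equal(shannon_index(rep(0.25, 4)), 2)
  expect_equal(shannon_index(1), 0)
  expect_equal(shannon_index(c(0.5, 0.25, 0.25)), 1.5)
  expect_error(shannon_index(c(-0.1, 1.1)), ">= 0")
  expect_error(shannon_index(c(0.4, 0.4)), "sum to 1")

  # Margalef (base-2 log)
  expect_equal(margalef_index(1, 100), 0)
  expect_equal(margalef_index(5, 16), 1)
  expect_equal(margalef_index(3, 8), 2 / 3)
  expect_true(is.na(margalef_index(3, 1)))

  # Pielou; frozen high-precision oracle for H' = 1.5, S = 3
  expect_equal(pielou_index(2, 4), 1)
  expect_true(is.na(pielou_index(0, 1)))
  expect_equal(pielou_index(1.5, 3), 0.9463946303571862, tolerance = 1e-12)

  # Simpson
  expect_equal(simpson_index(1), 0)
  expect_equal(simpson_index(c(0.5, 0.5)), 0.5)
  expect_equal(simpson_index(rep(1 / 8, 8)), 1 - 1 / 8)
})

test_that("index invariants hold on random communities", {
  set.seed(401)
  for (i in 1:50) {
    S <- sample(2:12, 1)
    p <- random_profile(S)
    H <- shannon_index(p)
    expect_lte(H, log2(S) + 1e-12)
    J <- pielou_index(H, S)
    expect_true(J >= 0 && J <= 1 + 1e-12)
    D <- simpson_index(p)
    expect_true(D >= 0 && D <= 1 - 1 / S + 1e-12)
  }
  # equality iff uniform
  expect_equal(shannon_index(rep(1 / 7, 7)), log2(7))
})

test_that("indices agree with brute-force re-evaluation to 1e-12", {
  set.seed(402)
  for (i in 1:20) {
    x <- stats::rexp(10) * 50
    p <- x / sum(x)
    H_brute <- 0
    D_brute <- 0
    for (pi in p) {
      if (pi > 0) H_brute <- H_brute - pi * log(pi) / log(2)
      D_brute <- D_brute + pi * pi
    }
    expect_equal(shannon_index(p), H_brute, tolerance = 1e-12)
    expect_equal(simpson_index(p), 1 - D_brute, tolerance = 1e-12)
  }
})

test_that("dominance uses pooled shares, occurrence, and a strict cutoff", {
  # one species everywhere: Y = 1
  rec <- data.frame(sample_id = c("s1", "s2"), stratum = "A", season = "Mar",
                    species_id = "sp1", n = c(5, 5), v = 1)
  d1 <- dominance(community_dataset(rec))
  expect_equal(d1$Y, 1)
  expect_true(d1$is_dominant)

  # constructed shares: Y = 0.025 dominant, Y = 0.020 not (strict).
  # focal: abundance 1 in `occ * 10` of 10 samples; one filler record
  # carries the rest of the mass so focal's pooled share is `share`.
  mk <- function(share, occ, n_samples = 10) {
    focal_total <- round(occ * n_samples)
    filler_total <- round(focal_total * (1 - share) / share)
    # filler in every sample (establishing the 10-sample universe),
    # integer counts, remainder folded into s1
    base <- floor(filler_total / n_samples)
    filler_n <- rep(base, n_samples)
    filler_n[1] <- filler_n[1] + (filler_total - base * n_samples)
    rec <- rbind(
      data.frame(sample_id = paste0("s", seq_len(focal_total)),
                 stratum = "A", season = "Mar", species_id = "focal",
                 n = 1, v = 1),
      data.frame(sample_id = paste0("s", seq_len(n_samples)),
                 stratum = "A", season = "Mar", species_id = "filler",
                 n = filler_n, v = 1))
    dominance(community_dataset(rec))
  }
  d <- mk(share = 0.05, occ = 0.5)
  focal <- d[d$species_id == "focal", ]
  expect_equal(focal$Y, 0.025, tolerance = 1e-12)
  expect_true(focal$is_dominant)

  # boundary case chosen binary-exact: (5/125) * (5/10) halves the double
  # 0.04 exactly, so Y == 0.02 to the last bit and the strict rule bites
  d <- mk(share = 0.04, occ = 0.5)
  focal <- d[d$species_id == "focal", ]
  expect_identical(focal$Y, 0.02)
  expect_false(focal$is_dominant)

  # shares sum to 1 over the scope
  expect_equal(sum(d$n_share), 1, tolerance = 1e-12)
})

test_that("dominance rejects empty or unknown scopes", {
  ds <- community_dataset(toy_records())
  expect_error(dominance(ds, samples = "nope"), "unknown sample")
})

test_that("composition percentages render survey-style class shares", {
  counts <- c(rotifer = 19, copepod = 19, protozoan = 13, other = 11,
              cladoceran = 7)
  cp <- composition_percentages(counts)
  expect_equal(cp$percent[cp$class == "rotifer"], 27.54)
  expect_equal(cp$percent[cp$class == "protozoan"], 18.84)
  expect_equal(cp$percent[cp$class == "other"], 15.94)
  expect_equal(cp$percent[cp$class == "cladoceran"], 10.14)
  expect_equal(sum(cp$fraction), 1, tolerance = 1e-12)

  expect_equal(composition_percentages(c(only = 3))$percent, 100)
  expect_error(composition_percentages(c(a = 0, b = 0)), "zero total")
  expect_error(composition_percentages(1:3), "named")
})

test_that("Bray-Curtis similarity matches its closed forms", {
  expect_equal(bray_curtis(c(2, 3), c(2, 3)), 1)
  expect_equal(bray_curtis(c(2, 0), c(0, 2)), 0)
  expect_equal(bray_curtis(c(2, 2), c(2, 0)), 2 / 3)
  expect_true(is.na(bray_curtis(c(0, 0), c(0, 0))))
  expect_error(bray_curtis(1:2, 1:3), "equal length")

  # symmetry and scale invariance
  set.seed(403)
  for (i in 1:20) {
    x <- stats::rexp(6); y <- stats::rexp(6)
    expect_equal(bray_curtis(x, y), bray_curtis(y, x), tolerance = 1e-12)
    expect_equal(bray_curtis(3.7 * x, 3.7 * y), bray_curtis(x, y),
                 tolerance = 1e-12)
  }

  m <- matrix(c(2, 2, 2, 0, 0, 2), nrow = 2,
              dimnames = list(NULL, c("u1", "u2", "u3")))
  bc <- bray_curtis_matrix(m)
  expect_equal(diag(bc), c(u1 = 1, u2 = 1, u3 = 1))
  expect_equal(bc, t(bc))
})

test_that("diversity_table pools by stratum-season and handles counts", {
  scen <- small_scenario(seed = 21)
  ds <- generate_community(scen)
  div <- diversity_table(ds)
  expect_equal(nrow(div), nrow(ds$samples))
  expect_true(all(div$H_prime >= 0, na.rm = TRUE))

  pooled <- diversity_table(ds, by = "stratum_season")
  expect_equal(nrow(pooled), 4)  # 2 strata x 2 seasons
  # pooling can only add species
  expect_true(max(pooled$S) >= max(div$S))

  # with unit volumes counts and abundance agree
  div_counts <- diversity_table(ds, use = "counts")
  expect_equal(div_counts$H_prime, div$H_prime, tolerance = 1e-12)
})
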