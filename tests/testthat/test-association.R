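test_that("presence_absence binarises with a strict threshold", {
  m <- matrix(c(0, 0.3, 0.5, 0.7), 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  pm <- presence_absence(m)
  expect_equal(unclass(pm)[, "s1"], c(a = 0, b = 1))
  expect_equal(unname(unclass(presence_absence(m, threshold = 0.5))[, "s2"]),
               c(0, 1))
  expect_error(presence_absence(m[1, , drop = FALSE]), "2 entities")
  expect_error(presence_absence(m[, 1, drop = FALSE]), "2 sites")
})

test_that("variance ratio matches the closed-form complementary case", {
  # A at site 1 only, B at site 2 only: sigma = 0.5, richness constant
  pm <- presence_absence(matrix(c(1, 0, 0, 1), 2, byrow = TRUE,
                                dimnames = list(c("A", "B"), NULL)))
  ov <- overall_variance_ratio(pm)
  expect_equal(ov$sigma_T2, 0.5)
  expect_equal(ov$S_T2, 0)
  expect_equal(ov$VR, 0)
  expect_equal(ov$verdict, "negative")

  # two entities always co-occurring at half the sites: VR > 1
  co <- matrix(rep(c(1, 1, 0, 0), 2), 2, byrow = TRUE,
               dimnames = list(c("A", "B"), NULL))
  ov2 <- overall_variance_ratio(presence_absence(co))
  expect_gt(ov2$VR, 1)
  expect_equal(ov2$verdict, "positive")

  # degenerate: all ubiquitous
  expect_error(overall_variance_ratio(matrix(1, 2, 3)), "ubiquitous")
})

test_that("VR equals a from-scratch two-pass computation; W = N * VR", {
  set.seed(601)
  for (i in 1:25) {
    m <- random_presence(sample(3:10, 1), sample(5:15, 1))
    ov <- overall_variance_ratio(m)
    # independent two-pass oracle
    N <- ncol(m)
    p <- rowSums(m) / N
    sigma <- sum(p * (1 - p))
    Tj <- colSums(m)
    tbar <- sum(Tj) / N
    st2 <- sum((Tj - tbar)^2) / N
    expect_equal(ov$VR, st2 / sigma, tolerance = 1e-12)
    expect_identical(ov$W, ov$VR * N)
  }
})

test_that("chi-square acceptance bounds are monotone in alpha", {
  m <- random_presence(5, 10)
  a1 <- overall_variance_ratio(m, alpha = 0.05)
  a2 <- overall_variance_ratio(m, alpha = 0.10)
  expect_lt(a1$chi2_lower, a2$chi2_lower)
  expect_gt(a1$chi2_upper, a2$chi2_upper)
})

test_that("2x2 tables follow the standard cell convention", {
  pm <- rbind(A = c(1, 1, 0, 0), B = c(1, 0, 1, 0))
  expect_equal(contingency_2x2(pm, "A", "B"), c(a = 1, b = 1, c = 1, d = 1))

  same <- rbind(A = c(1, 1, 0), B = c(1, 1, 0))
  expect_equal(contingency_2x2(same, "A", "B"), c(a = 2, b = 0, c = 0, d = 1))

  comp <- rbind(A = c(1, 0), B = c(0, 1))
  tab <- contingency_2x2(comp, "A", "B")
  expect_equal(tab[["a"]], 0)
  expect_equal(tab[["d"]], 0)
})

test_that("phi matches closed forms and is NA on degenerate marginals", {
  expect_equal(point_correlation(2, 0, 0, 2), 1)
  expect_equal(point_correlation(0, 2, 2, 0), -1)
  expect_equal(point_correlation(1, 1, 1, 1), 0)
  # frozen hand-arithmetic oracle: (6*6 - 2*1) / sqrt(8*7*8*7) = 34/56
  expect_equal(point_correlation(6, 2, 1, 6), 0.6071428571428571,
               tolerance = 1e-12)
  expect_equal(point_correlation(c(6, 2, 1, 6)), 34 / 56)
  expect_true(is.na(point_correlation(3, 0, 2, 0)))  # B ubiquitous
  expect_false(is.infinite(point_correlation(3, 0, 2, 0)))
})

test_that("phi equals the Pearson correlation of the binary vectors", {
  set.seed(602)
  for (i in 1:40) {
    m <- random_presence(2, sample(6:20, 1))
    tab <- contingency_2x2(m, 1, 2)
    expect_equal(point_correlation(tab), stats::cor(m[1, ], m[2, ]),
                 tolerance = 1e-12)
  }
})

test_that("complement identities hold", {
  set.seed(603)
  for (i in 1:20) {
    m <- random_presence(2, 12)
    phi <- point_correlation(contingency_2x2(m, 1, 2))
    both <- 1 - m
    expect_equal(point_correlation(contingency_2x2(both, 1, 2)), phi,
                 tolerance = 1e-12)
    one <- m; one[2, ] <- 1 - one[2, ]
    expect_equal(point_correlation(contingency_2x2(one, 1, 2)), -phi,
                 tolerance = 1e-12)
  }
})

test_that("pair classification applies the 1-df chi-square rule", {
  # perfect co-occurrence over N = 10: chi2 = 10 > 3.8414588 (frozen
  # critical value from an independent quantile source)
  pat <- c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0)
  pm <- rbind(A = pat, B = pat, C = 1 - pat)
  pairs <- classify_pairs(pm)
  ab <- pairs[pairs$entity_a == "A" & pairs$entity_b == "B", ]
  expect_equal(ab$phi, 1)
  expect_equal(ab$chi2, 10)
  expect_equal(ab$class, "sig_positive")
  ac <- pairs[pairs$entity_a == "A" & pairs$entity_b == "C", ]
  expect_equal(ac$class, "sig_negative")

  # balanced table: phi = 0, non-significant, flagged zero
  pm0 <- rbind(A = c(1, 1, 0, 0), B = c(1, 0, 1, 0))
  p0 <- classify_pairs(pm0)
  expect_equal(p0$phi, 0)
  expect_equal(p0$class, "positive")
  expect_true(p0$zero_phi)

  # constant pattern -> undefined class
  pmc <- rbind(A = c(1, 1, 1), B = c(1, 0, 1))
  expect_equal(classify_pairs(pmc)$class, "undefined")
})

test_that("stability verdict follows the positive/negative balance", {
  mk_pairs <- function(classes)
    data.frame(class = classes, stringsAsFactors = FALSE)
  expect_equal(stability_summary(
    mk_pairs(c("positive", "positive", "sig_positive", "negative")))$verdict,
    "stable")
  expect_equal(stability_summary(
    mk_pairs(c("positive", "negative", "negative", "sig_negative")))$verdict,
    "successional")
  expect_equal(stability_summary(
    mk_pairs(c("positive", "negative")))$verdict, "indeterminate")

  # the field-survey-scale case: 21 positive vs 7 negative pairs
  s <- stability_summary(mk_pairs(c(rep("positive", 18), rep("sig_positive", 3),
                                    rep("negative", 5), rep("sig_negative", 2))))
  expect_equal(s$n_positive, 21)
  expect_equal(s$n_negative, 7)
  expect_equal(s$ratio, 3)
  expect_equal(s$verdict, "stable")
})

test_that("Pearson pair summary counts signs and strong pairs", {
  set.seed(604)
  base <- stats::rlnorm(10, 3, 1)
  m <- rbind(a = base, dup = base * 2,
             neg = max(base) + min(base) - base,
             flat = rep(5, 10))
  res <- pearson_pair_summary(m, log_transform = FALSE)
  expect_equal(res$skipped, "flat")
  dup_r <- res$pairs$r[res$pairs$entity_a == "a" & res$pairs$entity_b == "dup"]
  expect_equal(dup_r, 1, tolerance = 1e-12)
  neg_r <- res$pairs$r[res$pairs$entity_a == "a" & res$pairs$entity_b == "neg"]
  expect_equal(neg_r, -1, tolerance = 1e-12)
  expect_equal(res$n_strong, 1)
  expect_error(pearson_pair_summary(m[, 1:2]), "at least 3 samples")
})

test_that("network export drops undefined pairs and round-trips", {
  pm <- rbind(A = c(1, 1, 0, 0), B = c(1, 0, 1, 0), C = c(1, 1, 1, 1))
  pairs <- classify_pairs(pm)
  path <- tempfile(fileext = ".tsv")
  export_network(pairs, path)
  edges <- read_results(path)
  expect_equal(nrow(edges), 1)  # pairs with C are undefined
  expect_false(any(edges$class == "undefined"))
  expect_equal(edges$phi, 0)

  # empty edge list still writes a header
  pm_all_const <- rbind(A = c(1, 1), B = c(1, 1), C = c(0, 1))
  expect_error(overall_variance_ratio(presence_absence(matrix(1, 2, 2))))
  p2 <- classify_pairs(rbind(A = c(1, 1, 1), B = c(1, 1, 1), C = c(0, 1, 0)))
  path2 <- tempfile(fileext = ".tsv")
  export_network(p2, path2)
  expect_equal(nrow(read_results(path2)), 0)
})
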