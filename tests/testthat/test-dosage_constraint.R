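mexpr_fixture <- function() {
  # two species, one tissue "apex"; orthogroup totals controlled directly.
  # OG1..OG5 have 2 copies in both species; OG6 has 3 copies in spB.
  og <- orthogroup_table(data.frame(
    orthogroup_id = c(rep(c("OG1", "OG2", "OG3", "OG4", "OG5"), each = 4),
                      rep("OG6", 5)),
    species = c(rep(c("spA", "spA", "spB", "spB"), 5),
                "spA", "spA", "spB", "spB", "spB"),
    gene_id = c(paste0("g", 1:20), paste0("h", 1:5))))
  mk <- function(genes, vals) {
    matrix(vals, ncol = 1, dimnames = list(genes, "apex"))
  }
  list(og = og,
       mexpr = list(
         spA = mk(c(paste0("g", seq(1, 17, 4)), paste0("g", seq(2, 18, 4)),
                    "h1", "h2"),
                  c(10, 10, 10, 10, 10, 10, 10, 10, 10, 0, 5, 5)),
         spB = mk(c(paste0("g", seq(3, 19, 4)), paste0("g", seq(4, 20, 4)),
                    "h3", "h4", "h5"),
                  c(rep(5, 10), 5, 5, 5))))
}

test_that("retention requires exactly two positive copies in both species", {
  fx <- mexpr_fixture()
  ret <- retained_orthogroups("apex", "spA", "spB", fx$mexpr, fx$og)
  # OG5 excluded: gene g18 has zero mean in spA; OG6 excluded: 3 copies in spB
  expect_setequal(ret, c("OG1", "OG2", "OG3", "OG4"))
})

test_that("comparisons z-score log2 ratios and degenerate spreads warn", {
  fx <- mexpr_fixture()
  ret <- retained_orthogroups("apex", "spA", "spB", fx$mexpr, fx$og)
  # identical ratios for all retained orthogroups -> zero spread
  expect_warning(
    cmp <- dosage_comparisons("apex", "spA", "spB", ret, fx$mexpr, fx$og),
    "zero spread")
  expect_equal(cmp$z, rep(0, 4))
  expect_equal(cmp$p, rep(1, 4))
  expect_equal(cmp$log2_ratio, rep(1, 4))  # 20 vs 10 everywhere
})

test_that("z and p match the hand computation on crafted ratios", {
  # totals 2^lr vs 1 so that log2 ratios are exactly lr
  lr <- c(0, 0.1, -0.1, 2)
  og <- orthogroup_table(data.frame(
    orthogroup_id = rep(paste0("OG", 1:4), each = 4),
    species = rep(c("spA", "spA", "spB", "spB"), 4),
    gene_id = paste0("g", 1:16)))
  mexpr <- list(
    spA = matrix(rep(2^lr / 2, each = 2), ncol = 1,
                 dimnames = list(paste0("g", c(1, 2, 5, 6, 9, 10, 13, 14)),
                                 "apex")),
    spB = matrix(rep(0.5, 8), ncol = 1,
                 dimnames = list(paste0("g", c(3, 4, 7, 8, 11, 12, 15, 16)),
                                 "apex")))
  ret <- retained_orthogroups("apex", "spA", "spB", mexpr, og)
  cmp <- dosage_comparisons("apex", "spA", "spB", ret, mexpr, og)
  cmp <- cmp[match(paste0("OG", 1:4), cmp$orthogroup_id), ]
  expect_equal(cmp$log2_ratio, lr)
  z_exp <- (lr - mean(lr)) / stats::sd(lr)
  expect_equal(cmp$z, z_exp)
  for (i in 1:4) {
    expect_equal(cmp$p[i], oracle_norm_p_two_sided(z_exp[i]),
                 tolerance = 1e-9)
  }
})

test_that("orientation swap negates ratios and z but preserves p", {
  set.seed(61)
  og <- orthogroup_table(data.frame(
    orthogroup_id = rep(paste0("OG", 1:6), each = 4),
    species = rep(c("spA", "spA", "spB", "spB"), 6),
    gene_id = paste0("g", 1:24)))
  va <- stats::runif(12, 1, 20)
  vb <- stats::runif(12, 1, 20)
  mexpr <- list(
    spA = matrix(va, ncol = 1,
                 dimnames = list(paste0("g", sort(c(seq(1, 24, 4), seq(2, 24, 4)))), "apex")),
    spB = matrix(vb, ncol = 1,
                 dimnames = list(paste0("g", sort(c(seq(3, 24, 4), seq(4, 24, 4)))), "apex")))
  ret <- retained_orthogroups("apex", "spA", "spB", mexpr, og)
  fwd <- dosage_comparisons("apex", "spA", "spB", ret, mexpr, og)
  rev <- dosage_comparisons("apex", "spB", "spA", ret, mexpr, og)
  expect_equal(fwd$log2_ratio, -rev$log2_ratio)
  expect_equal(fwd$z, -rev$z)
  expect_equal(fwd$p, rev$p)
})

test_that("comparisons with too few orthogroups are skipped with a message", {
  fx <- mexpr_fixture()
  expect_message(
    cmp <- dosage_comparisons("apex", "spA", "spB", c("OG1", "OG2"),
                              fx$mexpr, fx$og),
    "skipping comparison")
  expect_equal(nrow(cmp), 0L)
})

test_that("bh_adjust matches the textbook step-up and its oracle", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_adjust(c(0.5, 0)), "0, 1")
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  set.seed(62)
  for (i in 1:50) {
    p <- stats::runif(sample(1:40, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(adj >= p))  # monotone: adjusted never below raw
  }
})

test_that("aggregation averages p within focal species and calls by BH", {
  cmp <- data.frame(
    tissue = "apex",
    focal = c("spA", "spA", "spA", "spA", "spB"),
    other = c("spB", "spC", "spB", "spC", "spA"),
    orthogroup_id = c("OG1", "OG1", "OG2", "OG2", "OG1"),
    total_focal = 1, total_other = 1, log2_ratio = 0,
    z = c(5, 4, 0, 0.5, -5),
    p = c(1e-8, 1e-6, 0.9, 0.6, 1e-8))
  calls <- aggregate_and_call(cmp, run_config(alpha = 0.05))
  a1 <- calls[calls$species == "spA" & calls$orthogroup_id == "OG1", ]
  expect_equal(a1$mean_p, mean(c(1e-8, 1e-6)))
  expect_equal(a1$n_comparisons, 2L)
  # BH within (spA, apex) over its two orthogroups
  expect_equal(
    calls$adj_p[calls$species == "spA"][order(calls$orthogroup_id[calls$species == "spA"])],
    bh_adjust(c(mean(c(1e-8, 1e-6)), mean(c(0.9, 0.6)))))
  expect_equal(a1$call, "unconstrained")
  expect_equal(calls$call[calls$species == "spA" &
                            calls$orthogroup_id == "OG2"], "constrained")
  # single comparison: mean_p is that p
  b1 <- calls[calls$species == "spB", ]
  expect_equal(b1$mean_p, 1e-8)

  allone <- cmp
  allone$p <- 1
  expect_true(all(aggregate_and_call(allone)$call == "constrained"))
})

test_that("optional |z| cutoff vetoes small-z calls", {
  cmp <- data.frame(tissue = "apex", focal = "spA", other = "spB",
                    orthogroup_id = c("OG1", "OG2"),
                    total_focal = 1, total_other = 1, log2_ratio = 0,
                    z = c(1.2, 8), p = c(0.001, 0.001))
  base <- aggregate_and_call(cmp)
  expect_equal(base$call, c("unconstrained", "unconstrained"))
  strict <- aggregate_and_call(cmp, run_config(z_min = 3))
  expect_equal(strict$call[strict$orthogroup_id == "OG1"], "constrained")
  expect_equal(strict$call[strict$orthogroup_id == "OG2"], "unconstrained")
})

test_that("dosage_test skips tissues present in fewer than two species", {
  sim <- tiny_sim(seed = 14)
  mexpr <- mean_expression_by_species(sim$datasets)
  # give spB an extra private tissue by renaming one column
  colnames(mexpr$sp02)[1] <- "prickle"
  res <- dosage_test(mexpr, sim$orthogroups)
  expect_false("prickle" %in% res$comparisons$tissue)
  expect_false("prickle" %in% res$calls$tissue)
  # roll-up marks an orthogroup unconstrained if any tissue is
  roll <- res$species_calls
  dt <- merge(res$calls, roll, by = c("orthogroup_id", "species"))
  agg <- tapply(dt$call.x == "unconstrained",
                paste(dt$orthogroup_id, dt$species), any)
  expect_equal(as.vector(agg[paste(roll$orthogroup_id, roll$species)]),
               roll$call == "unconstrained")
})
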