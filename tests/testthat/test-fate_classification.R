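test_that("paralogue_pairs enumerates all within-species combinations", {
  og <- orthogroup_table(data.frame(
    orthogroup_id = c("OG1", "OG1", "OG1", "OG2", "OG2"),
    species = c("spA", "spA", "spA", "spA", "spB"),
    gene_id = c("a1", "a2", "a3", "x1", "y1")))
  p <- paralogue_pairs(og)
  expect_equal(nrow(p), 3L)  # 3 choose 2 within OG1/spA; OG2 has singletons
  expect_setequal(paste(p$gene_a, p$gene_b),
                  c("a1 a2", "a1 a3", "a2 a3"))
  ann <- data.frame(species = "spA", gene_a = "a2", gene_b = "a1",
                    dup_type = "tandem", ks = 0.4)
  p2 <- paralogue_pairs(og, annotations = ann)
  expect_equal(p2$dup_type[p2$gene_a == "a1" & p2$gene_b == "a2"], "tandem")
  expect_equal(sum(!is.na(p2$ks)), 1L)
})

test_that("fold_change_stats matches hand computation and symmetry", {
  ds <- make_dataset(rbind(a = c(4, 8, 2), b = c(1, 2, 1)),
                     tissues = rep("apex", 3))
  fc <- fold_change_stats("a", "b", ds)
  expect_equal(fc$mean_abs_l2fc, mean(c(2, 2, 1)))
  expect_equal(fc$sd_l2fc, stats::sd(c(2, 2, 1)))
  expect_equal(fc$n_samples_used, 3L)
  # orientation invariance
  rev <- fold_change_stats("b", "a", ds)
  expect_equal(rev$mean_abs_l2fc, fc$mean_abs_l2fc)
  expect_equal(rev$sd_l2fc, fc$sd_l2fc)

  ds2 <- make_dataset(rbind(a = c(3, 5, 7), b = c(3, 5, 7)),
                      tissues = rep("apex", 3))
  fc2 <- fold_change_stats("a", "b", ds2)
  expect_equal(fc2$mean_abs_l2fc, 0)
  expect_equal(fc2$sd_l2fc, 0)

  ds3 <- make_dataset(rbind(a = c(1, 2, 3), b = c(4, 8, 12)),
                      tissues = rep("apex", 3))
  fc3 <- fold_change_stats("a", "b", ds3)
  expect_equal(fc3$mean_abs_l2fc, 2)   # uniform 4-fold scaling
  expect_equal(fc3$sd_l2fc, 0)

  # zero-expression samples are excluded; < 2 usable samples -> insufficient
  ds4 <- make_dataset(rbind(a = c(4, 0, 2), b = c(0, 2, 1)),
                      tissues = rep("apex", 3))
  fc4 <- fold_change_stats("a", "b", ds4)
  expect_equal(fc4$n_samples_used, 1L)
  expect_true(is.na(fc4$mean_abs_l2fc))
})

test_that("classify_pair reproduces the quoted rules and boundaries", {
  expect_equal(classify_pair(0.95, 0.3, 0.4), "I")
  expect_equal(classify_pair(0.95, 1.5, 0.4), "II")
  expect_equal(classify_pair(0.95, 1.5, 1.5), "III")
  expect_equal(classify_pair(0.30, 1.5, 1.5), "IV")
  # strict coexpression boundary: exactly 0.9 is a threshold gap
  expect_equal(classify_pair(0.9, 0.3, 0.4), "none")
  # non-strict fold-change boundary: mean exactly 1 is on the II/III side
  expect_equal(classify_pair(0.95, 1, 0.4), "II")
  expect_equal(classify_pair(0.95, 1, 1), "III")
  expect_equal(classify_pair(0.5, 1.5, 1.5), "none")
  expect_equal(classify_pair(0.3, 0.5, 1.5), "none")
  expect_equal(classify_pair(0.95, 0.5, 1.5), "none")
})

test_that("classification agrees with rule restatement on random triples", {
  set.seed(51)
  n <- 2000
  triples <- cbind(stats::runif(n), stats::runif(n, 0, 3),
                   stats::runif(n, 0, 3))
  # force boundary values into the sweep
  triples[1:6, 1] <- c(0.9, 0.9, 0.5, 0.5, 0.95, 0.3)
  triples[1:6, 2] <- c(0.5, 1, 1, 1, 1, 1)
  triples[1:6, 3] <- c(0.5, 1, 1, 0.5, 1, 1)
  for (i in seq_len(n)) {
    expect_identical(
      classify_pair(triples[i, 1], triples[i, 2], triples[i, 3]),
      oracle_classify(triples[i, 1], triples[i, 2], triples[i, 3]))
  }
})

test_that("pair_filter buckets match the funnel contract", {
  v <- rbind(hi1 = c(9, 9, 9), hi2 = c(8, 9, 8),
             solo1 = c(7, 5, 0), solo2 = c(0, 7, 7),
             zero = c(0, 0, 0), low = c(1, 1, 1))
  ds <- make_dataset(v, tissues = rep("apex", 3))
  sub <- median_expression_subset(ds)
  expect_false("zero" %in% sub)
  expect_equal(pair_filter("zero", "hi1", ds, sub), "low_or_no_expression")
  expect_equal(pair_filter("low", "hi1", ds, sub), "low_or_no_expression")
  # both pass the subset but overlap in a single non-zero sample
  expect_true(all(c("solo1", "solo2") %in% sub))
  expect_equal(pair_filter("solo1", "solo2", ds, sub), "insufficient")
  expect_equal(pair_filter("hi1", "hi2", ds, sub), "eligible")
})

test_that("classify_all buckets partition pairs and match per-pair calls", {
  pipe <- run_pipeline(tiny_sim(seed = 5))
  pairs <- paralogue_pairs(pipe$sim$orthogroups)
  res <- classify_all(pairs, pipe$datasets, pipe$networks)
  rec <- res$records
  expect_equal(nrow(rec), nrow(pairs))
  expect_equal(sum(unlist(res$funnel$bucket_counts)), nrow(pairs))
  expect_equal(sum(unlist(res$funnel$bucket_fractions)), 1)
  expect_true(all((rec$group != "none") == (rec$bucket == "classified")))

  # spot-check the vectorized path against the per-pair functions
  set.seed(52)
  for (i in sample(nrow(rec), 25)) {
    sp <- rec$species[i]
    ds <- pipe$datasets[[sp]]
    nw <- pipe$networks[[sp]]
    bk <- pair_filter(rec$gene_a[i], rec$gene_b[i], ds, nw$genes, nw)
    if (bk == "eligible") {
      fc <- fold_change_stats(rec$gene_a[i], rec$gene_b[i], ds)
      w <- pair_coexpression(nw, rec$gene_a[i], rec$gene_b[i])
      expect_equal(rec$coexpression[i], w)
      expect_equal(rec$mean_abs_l2fc[i], fc$mean_abs_l2fc)
      expect_equal(rec$sd_l2fc[i], fc$sd_l2fc)
      expect_identical(rec$group[i],
                       classify_pair(w, fc$mean_abs_l2fc, fc$sd_l2fc))
    } else {
      expect_identical(rec$bucket[i], bk)
    }
  }
  expect_error(
    classify_all(data.frame(species = names(pipe$datasets)[1],
                            orthogroup_id = "OGX", gene_a = "ghost",
                            gene_b = "ghost2"),
                 pipe$datasets, pipe$networks),
    "absent from expression matrix: ghost")
})

test_that("relaxing thresholds only moves pairs out of the threshold gap", {
  pipe <- run_pipeline(tiny_sim(seed = 5))
  pairs <- paralogue_pairs(pipe$sim$orthogroups)
  strict <- classify_all(pairs, pipe$datasets, pipe$networks)$records
  relaxed_cfg <- run_config(coexpr_high = 0.7, coexpr_low = 0.7)
  relaxed <- classify_all(pairs, pipe$datasets, pipe$networks,
                          relaxed_cfg)$records
  was_classified <- strict$bucket == "classified"
  expect_true(all(relaxed$bucket[was_classified] == "classified"))
  expect_lte(sum(relaxed$bucket == "threshold_gap"),
             sum(strict$bucket == "threshold_gap"))
})

test_that("shared_expression_domains intersects breadths", {
  # a expressed in {apex, leaves}, b in {coty, inflo, leaves}: overlap 1
  m <- rbind(a = c(apex = 10, coty = 2, hypo = 0, inflo = 0, leaves = 8),
             b = c(apex = 1, coty = 9, hypo = 0, inflo = 5, leaves = 7))
  expect_equal(shared_expression_domains("a", "b", m), 1L)
  m2 <- m; m2[] <- 10
  expect_equal(shared_expression_domains("a", "b", m2), 5L)
  set.seed(53)
  for (i in 1:10) {
    mm <- matrix(stats::runif(10, 0, 8), 2,
                 dimnames = list(c("a", "b"), paste0("t", 1:5)))
    brute <- sum(vapply(1:5, function(t) mm[1, t] > 3 && mm[2, t] > 3,
                        logical(1)))
    expect_equal(shared_expression_domains("a", "b", mm), brute)
  }
})

test_that("WGD/SSD stratification applies the closed Ks windows", {
  rec <- data.frame(
    bucket = "classified", group = c("I", "II", "III", "IV", "I", "I", "II"),
    dup_type = c("WGD", "WGD", "tandem", "proximal", "WGD", "tandem",
                 "dispersed"),
    ks = c(0.2, 0.1, 2.5, 0.04, NA, 1, 1))
  s <- wgd_ssd_summary(rec)
  # WGD at Ks 0.2 is inside the closed window, 0.1 outside, NA excluded;
  # tandem at 2.5 inside, proximal at 0.04 outside, dispersed never SSD here
  expect_equal(sum(s$n[s$origin == "WGD"]), 1L)
  expect_equal(sum(s$n[s$origin == "SSD"]), 2L)
  expect_equal(s$n[s$origin == "SSD" & s$group == "III"], 1L)
})
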