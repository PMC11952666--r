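test_that("stable-site selection ranks by across-sample variance", {
  set.seed(30)
  x <- matrix(stats::rnorm(1000 * 6, 20, 1), 1000, 6,
              dimnames = list(sprintf("s%04d", 1:1000), paste0("S", 1:6)))
  x[1:5, ] <- 7                        # exactly constant sites rank first
  sel <- select_stable_sites(x, fraction = 0.01)
  expect_true(all(sprintf("s%04d", 1:5) %in% sel[1:5]))
  expect_length(select_stable_sites(x, fraction = 1), 1000L)
  expect_error(select_stable_sites(x, fraction = 0), "fraction")
  # planted low-variance block is recovered at the matching fraction
  x2 <- matrix(stats::rnorm(1000 * 6, 20, 1), 1000, 6,
               dimnames = dimnames(x))
  x2[101:200, ] <- 15 + stats::rnorm(100 * 6, 0, 0.05)
  sel2 <- select_stable_sites(x2, fraction = 0.1)
  expect_gte(length(intersect(sel2, sprintf("s%04d", 101:200))), 95L)
})

test_that("batch correction removes additive offsets and is idempotent", {
  set.seed(31)
  x <- matrix(stats::rnorm(300 * 8, 20, 0.3), 300, 8,
              dimnames = list(sprintf("s%03d", 1:300), paste0("S", 1:8)))
  stable <- select_stable_sites(x, 0.2)
  # single batch: identity
  expect_identical(batch_correct(x, rep(1L, 8), stable), x)
  # +1 offset on half the samples is removed (stable sites near offset-free)
  batches <- rep(c(1L, 2L), each = 4L)
  xb <- x
  xb[, batches == 2L] <- xb[, batches == 2L] + 1
  corr <- batch_correct(xb, batches, stable)
  ref <- batch_correct(x, batches, stable)
  expect_lt(max(abs(corr[stable, ] - ref[stable, ])), 0.05)
  # applying the correction twice changes nothing
  expect_equal(batch_correct(corr, batches, stable), corr,
               tolerance = 1e-9)
  expect_error(batch_correct(x, batches, character(0)), "stable")
})

test_that("protein normalization is exact in the noise-free limit and
           flags missing parents", {
  g <- two_group_factor(4L)
  study <- simulate_study(sim_config(n_proteins = 200L,
                                     n_phosphosites = 150L,
                                     kinase_shift = rep(0, 5),
                                     noise_sd = 0.5, site_noise_sd = 0,
                                     frac_de = 0.1, n_modules = 0L,
                                     seed = 32L))
  norm <- suppressMessages(normalize_site_by_protein(
    study$phospho$matrix, study$proteome$matrix, study$phospho$site_table, g
  ))
  # purely protein-driven sites: fc_norm = 0 to machine precision
  expect_lt(max(abs(norm$stats$fc_norm)), 1e-9)
  # simple cancellation check on a hand-built pair
  px <- matrix(c(1, 1, 1, 1, 2, 2, 2, 2), 1, 8,
               dimnames = list("P1", paste0("S", 1:8)))
  sx <- px + 0
  rownames(sx) <- "P1;S10"
  tab <- data.frame(site_id = "P1;S10", protein_id = "P1")
  n1 <- suppressMessages(normalize_site_by_protein(
    rbind(sx, sx + 0.01 * matrix(stats::rnorm(8), 1)), rbind(px, px),
    rbind(tab, data.frame(site_id = "P1;S11", protein_id = "P1")), g
  ))
  expect_equal(n1$stats$fc_norm[1L], 0)
  # undetected parent: fold change passes through, flagged unnormalized
  sx2 <- matrix(stats::rnorm(8, 20, 1e-9), 1, 8,
                dimnames = list("PX;S5", paste0("S", 1:8)))
  sx2[, 5:8] <- sx2[, 5:8] - 0.8
  sm <- rbind(sx2, sx2 + 0.001)
  rownames(sm) <- c("PX;S5", "PX;S6")
  pm <- rbind(px, px)
  rownames(pm) <- c("P1", "P2")
  n2 <- suppressMessages(normalize_site_by_protein(
    sm, pm,
    data.frame(site_id = c("PX;S5", "PX;S6"),
               protein_id = c("PX", "PX")), g
  ))
  expect_false(n2$stats$normalized[1L])
  expect_equal(n2$stats$fc_norm[1L], -0.8, tolerance = 1e-6)
})

test_that("motif scores follow log-odds and the percentile convention", {
  cfg <- sim_config(n_kinases = 1L, motif_sharpness = 0.9, seed = 33L)
  pssm <- simulate_kinase_models(cfg)[[1L]]
  consensus <- paste(colnames(pssm)[apply(pssm, 1L, which.max)],
                     collapse = "")
  set.seed(34)
  bg <- vapply(1:50, function(i) {
    w <- sample(colnames(pssm), 15L, replace = TRUE)
    w[8L] <- "S"
    paste(w, collapse = "")
  }, character(1))
  sc <- motif_score(c(consensus, bg), pssm)
  expect_equal(sc$score[1L], 1)            # argmax consensus tops any set
  # uniform PSSM: all windows tie at 0.5
  flat <- matrix(1 / 20, 15, 20, dimnames = dimnames(pssm))
  expect_equal(motif_score(bg, flat)$score, rep(0.5, 50))
  # hand-computed log-odds ordering on a 3-site fixture
  p3 <- flat
  p3[5L, ] <- c(0.81, rep(0.01, 19))       # prefers A at position 5
  w1 <- paste(c(rep("A", 7), "S", rep("A", 7)), collapse = "")
  w2 <- paste(c(rep("C", 4), "A", rep("C", 2), "S", rep("C", 7)),
              collapse = "")
  w3 <- paste(c(rep("C", 7), "S", rep("C", 7)), collapse = "")
  s3 <- motif_score(c(w3, w1, w2), p3)
  raw_hit <- log(0.81 / 0.05) / 15
  raw_miss <- log(0.01 / 0.05) / 15
  expect_equal(s3$raw, c(raw_miss, raw_hit, raw_hit), tolerance = 1e-12)
  # percentiles: w3 lowest (0), w1/w2 tie at the averaged rank
  expect_equal(s3$score, c(0, 0.75, 0.75), tolerance = 1e-12)
  expect_warning(motif_score(paste(rep("Z", 15), collapse = ""), pssm),
                 "unknown residue")
})

test_that("profile scores rescale correlation with the centroid", {
  set.seed(35)
  centroid <- as.numeric(scale(stats::rnorm(8)))
  profs <- rbind(centroid, -centroid, stats::rnorm(8))
  # orthogonalize the third profile against the centroid exactly
  profs[3L, ] <- stats::residuals(stats::lm(profs[3L, ] ~ centroid))
  s <- profile_score(profs, centroid)
  expect_equal(s[1L], 1)
  expect_equal(s[2L], 0)
  expect_equal(s[3L], 0.5, tolerance = 1e-9)
  # zero-variance profile: 0.5 with flag
  sflat <- profile_score(rbind(rep(1, 8)), centroid)
  expect_equal(as.numeric(sflat), 0.5)
  expect_true(attr(sflat, "flat")[1L])
})

test_that("combined score is the weighted geometric mean and monotone", {
  expect_equal(combined_substrate_score(1, 1), 1)
  expect_equal(combined_substrate_score(0, 0.7), 0)
  expect_equal(combined_substrate_score(0.64, 0.25), 0.4)
  grid <- seq(0, 1, by = 0.1)
  for (w in c(0.3, 0.5, 0.8)) {
    m <- outer(grid, grid, combined_substrate_score, w = w)
    expect_true(all(diff(m) >= -1e-12))          # monotone in motif
    expect_true(all(t(diff(t(m))) >= -1e-12))    # monotone in profile
  }
  expect_error(combined_substrate_score(0.5, 0.5, w = 1.5), "w")
})

test_that("PU prediction separates true substrates and is deterministic", {
  study <- simulate_study(kinase_recovery_config(36L))
  res <- run_kinase_inference(study, seed = 36L)
  sc <- res$scores
  for (k in c("K1", "K2")) {
    sck <- sc[sc$kinase == k, ]
    truth <- sck$site_id %in% study$phospho$truth$substrate_map[[k]]
    expect_gt(auroc(sck$pu_probability, truth), 0.8)
    ann <- study$phospho$annotation$site_id[
      study$phospho$annotation$kinase == k]
    expect_gte(min(sck$pu_probability[sck$site_id %in% ann]),
               stats::median(sck$pu_probability[!sck$site_id %in% ann]))
  }
  # seeded determinism
  res2 <- run_kinase_inference(study, seed = 36L)
  expect_identical(res$scores$pu_probability, res2$scores$pu_probability)
  # too few positives: fallback to combined score with warning
  sck <- sc[sc$kinase == "K1", ]
  expect_warning(fb <- pu_predict(sck, sck$site_id[1:3]), "fewer than 5")
  expect_identical(fb, sck$combined)
})

test_that("substrate ranking is complete, deterministic and hand-checkable", {
  fix <- data.frame(
    site_id = sprintf("P%02d;S1", 1:20), kinase = "K1",
    motif = seq(0.05, 1, length.out = 20),
    profile = 0.5,
    combined = c(10:1, 10:1) / 10,
    pu_probability = c(10:1, 10:1) / 10
  )
  top <- rank_top_substrates(fix, "K1", n = 5L)
  # ties on pu broken by motif (descending): the later duplicate wins
  expect_equal(top, c("P11;S1", "P01;S1", "P12;S1", "P02;S1", "P13;S1"))
  all20 <- rank_top_substrates(fix, "K1", n = 20L)
  expect_setequal(all20, fix$site_id)
  expect_identical(rank_top_substrates(fix, "K1", n = 5L), top)
  expect_error(rank_top_substrates(fix, "K1", n = 0L), "positive")
})

test_that("kinase activity summarises substrate changes with a t-test", {
  ns <- data.frame(site_id = sprintf("s%02d", 1:40),
                   fc_norm = rep(0, 40))
  a0 <- kinase_activity(ns, ns$site_id[1:10], "K")
  expect_equal(a0$activity_score, 0)
  expect_equal(a0$direction, "unchanged")
  # symmetric +/-1 pairs: activity 0
  ns$fc_norm <- rep(c(1, -1), 20)
  asym <- kinase_activity(ns, ns$site_id[1:10], "K")
  expect_equal(asym$activity_score, 0, tolerance = 1e-12)
  # fewer than 3 substrates: p is NA
  expect_true(is.na(kinase_activity(ns, ns$site_id[1:2], "K")$p))
  expect_error(kinase_activity(ns, character(0)), "empty")
})

test_that("shifted kinases are recovered with the right direction", {
  hits <- 0L
  dominant <- 0L
  seeds <- 41:45
  for (s in seeds) {
    study <- simulate_study(kinase_recovery_config(s))
    res <- run_kinase_inference(study, seed = s)
    act <- do.call(rbind, lapply(names(study$kinase_models), function(k) {
      subs <- rank_top_substrates(res$scores, k, n = 30L)
      kinase_activity(res$norm$stats, subs, kinase = k)
    }))
    ok <- act$direction[act$kinase == "K1"] == "down" &&
      act$p[act$kinase == "K1"] < 0.05 &&
      act$direction[act$kinase == "K2"] == "up" &&
      act$p[act$kinase == "K2"] < 0.05
    hits <- hits + ok
    # shifted kinases dominate unshifted ones in |activity|
    shifted <- min(abs(act$activity_score[act$kinase %in% c("K1", "K2")]))
    unshifted <- max(abs(act$activity_score[!act$kinase %in% c("K1", "K2")]))
    dominant <- dominant + (shifted > unshifted)
  }
  expect_gte(hits, length(seeds) - 1L)
  expect_gte(dominant, length(seeds) - 1L)
})

test_that("consensus-substrate mapping classifies trends by FDR and SD", {
  ann <- data.frame(kinase = "PKA", site_id = sprintf("s%02d", 1:10))
  st <- data.frame(
    site_id = sprintf("s%02d", 1:12),
    fc_norm = c(0.9, -0.8, 0.2, 0.5, -0.45, 1.2, -1.0, 0.05, 0.6, -0.7,
                2, 2),
    q_bh = c(0.01, 0.05, 0.01, 0.3, 0.1, 0.15, 0.19, 0.01, 0.21, 0.18,
             0.01, 0.01)
  )
  out <- map_consensus_substrates(st, ann, "PKA", sd_hat = 0.41,
                                  fdr_cut = 0.2, sd_multiple = 1)
  # brute-force expectation over the ten matched sites
  m <- st[1:10, ]
  sig <- m$q_bh < 0.2
  want_up <- sum(sig & m$fc_norm > 0.41)
  want_dn <- sum(sig & m$fc_norm < -0.41)
  expect_equal(unname(out$counts["n_matched"]), 10L)
  expect_equal(unname(out$counts["n_up"]), want_up)
  expect_equal(unname(out$counts["n_down"]), want_dn)
  expect_equal(unname(out$counts["n_flat"]), 10L - want_up - want_dn)
  # sd_multiple = 0: every FDR-passing site classified by sign
  out0 <- map_consensus_substrates(st, ann, "PKA", sd_hat = 0.41,
                                   sd_multiple = 0)
  expect_equal(unname(out0$counts["n_up"] + out0$counts["n_down"]),
               sum(sig & m$fc_norm != 0))
  # disjoint annotation: empty result, no error
  out_empty <- map_consensus_substrates(st,
                                        data.frame(kinase = "PKA",
                                                   site_id = "zz"),
                                        "PKA", sd_hat = 0.41)
  expect_equal(unname(out_empty$counts["n_matched"]), 0L)
})

test_that("substrate scoring is invariant to site and sample ordering", {
  study <- simulate_study(sim_config(n_proteins = 150L,
                                     n_phosphosites = 200L, seed = 46L))
  res <- run_kinase_inference(study, seed = 46L)
  # permute sites
  perm <- sample(nrow(study$phospho$matrix))
  study2 <- study
  study2$phospho$matrix <- study$phospho$matrix[perm, ]
  res2 <- run_kinase_inference(study2, seed = 46L)
  a <- res$scores[order(res$scores$kinase, res$scores$site_id), ]
  b <- res2$scores[order(res2$scores$kinase, res2$scores$site_id), ]
  expect_equal(a$motif, b$motif, tolerance = 1e-12)
  expect_equal(a$profile, b$profile, tolerance = 1e-12)
  expect_equal(a$combined, b$combined, tolerance = 1e-12)
})

test_that("rank-based AUROC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(70)
  for (i in 1:5) {
    lab <- stats::rbinom(60, 1, 0.4)
    if (length(unique(lab)) < 2L) next
    sc <- stats::rnorm(60) + lab
    ref <- suppressMessages(as.numeric(pROC::auc(lab, sc,
                                                 direction = "<")))
    expect_equal(auroc(sc, lab), ref, tolerance = 1e-12)
  }
  expect_error(auroc(1:3, c(1, 1, 1)), "positive")
})
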