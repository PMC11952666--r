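test_that("signed adjacency follows the correlation transform", {
  # perfectly correlated / anti-correlated / independent pairs
  s <- seq(-1, 1, length.out = 8)
  x <- rbind(a = s, b = s, c = -s)
  adj <- signed_adjacency(x, power = 6)
  expect_equal(adj["a", "b"], 1)
  expect_equal(adj["a", "c"], 0, tolerance = 1e-12)
  # cor = 0 at beta = 10 gives (1/2)^10
  set.seed(50)
  u <- stats::rnorm(10)
  v <- stats::residuals(stats::lm(stats::rnorm(10) ~ u))
  a2 <- signed_adjacency(rbind(u = u, v = v), power = 10)
  expect_equal(a2["u", "v"], 0.5^10, tolerance = 1e-12)
  expect_error(signed_adjacency(rbind(u, rep(1, 10)), 6), "zero-variance")
  expect_error(signed_adjacency(rbind(u, v), 0.5), "power")
})

test_that("TOM matches the formula and a brute-force implementation", {
  # two isolated nodes, a = 0.5: hand evaluation of the formula
  # (k1 = k2 = 0.5, no shared neighbors)
  a <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  expect_equal(tom_similarity(a)[1, 2], 0.5 / (0.5 + 1 - 0.5))
  # identical rows with a_ij = 1: maximal overlap
  a3 <- matrix(1, 3, 3)
  expect_equal(tom_similarity(a3)[1, 2], 1)
  # random 8-node adjacency vs triple-loop oracle
  set.seed(51)
  cm <- stats::cov2cor(crossprod(matrix(stats::rnorm(80), 10, 8)))
  A <- ((1 + cm) / 2)^4
  diag(A) <- 1
  expect_lt(max(abs(tom_similarity(A) - tom_brute(A))), 1e-12)
  expect_error(tom_similarity(matrix(stats::runif(9), 3, 3)), "symmetric")
})

test_that("soft-threshold scan obeys its selection rules", {
  # independent noise: no power reaches the target, plateau fallback warns
  set.seed(52)
  x0 <- matrix(stats::rnorm(300 * 8), 300, 8,
               dimnames = list(sprintf("f%03d", 1:300), NULL))
  expect_warning(scan0 <- pick_soft_threshold(x0), "plateau")
  expect_false(scan0$reached_target)
  # mean connectivity strictly decreasing in the power on any input
  expect_true(all(diff(scan0$table$mean_k) < 0))
  pr <- simulate_proteome(module_recovery_config(53L))
  scan1 <- suppressWarnings(pick_soft_threshold(pr$matrix))
  expect_true(all(diff(scan1$table$mean_k) < 0))
  # the plateau fallback lands near the asymptotic fit
  expect_gte(scan1$table$signed_r2[scan1$table$power == scan1$power],
             max(scan1$table$signed_r2, na.rm = TRUE) - 0.02)
  # constant features dropped with a warning
  xc <- rbind(x0, constant = rep(1, 8))
  warns <- testthat::capture_warnings(pick_soft_threshold(xc))
  expect_true(any(grepl("constant", warns)))
})

test_that("module detection separates blocks and handles degeneracy", {
  # two perfectly separated blocks
  d <- matrix(1, 8, 8)
  d[1:4, 1:4] <- 0
  d[5:8, 5:8] <- 0
  diag(d) <- 0
  rownames(d) <- colnames(d) <- paste0("f", 1:8)
  lab <- detect_modules(d, min_size = 3L)
  expect_equal(as.integer(lab), c(1L, 1L, 1L, 1L, 2L, 2L, 2L, 2L))
  # all-equal dissimilarity: everything unassigned
  d2 <- matrix(0.5, 6, 6)
  diag(d2) <- 0
  rownames(d2) <- colnames(d2) <- paste0("g", 1:6)
  expect_equal(as.integer(detect_modules(d2, min_size = 2L)), rep(0L, 6))
  # min_size larger than the matrix: warning, all unassigned
  expect_warning(lab3 <- detect_modules(d, min_size = 10L), "min_size")
  expect_equal(as.integer(lab3), rep(0L, 8))
})

test_that("eigengenes explain rank-1 modules and merge redundant ones", {
  set.seed(54)
  f <- stats::rnorm(8)
  # module of exact copies: variance explained 1, ME tracks the profile
  x <- matrix(rep(f, each = 6), 6, 8,
              dimnames = list(paste0("p", 1:6), paste0("S", 1:8)))
  ms <- eigengenes_and_merge(x, rep(1L, 6))
  expect_equal(ms$var_explained[["ME1"]], 1)
  expect_equal(abs(stats::cor(ms$eigengenes["ME1", ], f)), 1)
  expect_equal(sum(ms$eigengenes["ME1", ]^2), 1)  # unit norm
  # two modules driven by one factor merge at merge_cut = 0.25
  x2 <- rbind(matrix(rep(f, each = 5), 5, 8) +
                matrix(stats::rnorm(40, 0, 0.1), 5),
              matrix(rep(f, each = 5), 5, 8) +
                matrix(stats::rnorm(40, 0, 0.1), 5))
  dimnames(x2) <- list(paste0("q", 1:10), paste0("S", 1:8))
  ms2 <- eigengenes_and_merge(x2, rep(c(1L, 2L), each = 5L))
  expect_length(ms2$sizes, 1L)
  expect_equal(nrow(ms2$merge_history), 1L)
  # sign convention: cor(ME, module mean profile) >= 0 on random data
  for (i in 1:20) {
    xr <- matrix(stats::rnorm(80), 10, 8,
                 dimnames = list(paste0("r", 1:10), paste0("S", 1:8)))
    msr <- eigengenes_and_merge(xr, rep(1L, 10), merge_cut = 0)
    zr <- t(scale(t(xr)))
    expect_gte(stats::cor(msr$eigengenes["ME1", ], colMeans(zr)), 0)
  }
})

test_that("module-trait statistics use the t-distribution closed form", {
  set.seed(55)
  trait <- rep(c(0, 1), each = 4)
  x <- matrix(stats::rnorm(48), 6, 8,
              dimnames = list(paste0("p", 1:6), paste0("S", 1:8)))
  ms <- eigengenes_and_merge(x, rep(1L, 6))
  # closed form: p = 2*pt(-|r|*sqrt((n-2)/(1-r^2)), n-2)
  mt <- module_trait_stats(ms, trait)
  r <- stats::cor(ms$eigengenes["ME1", ], trait)
  expect_equal(mt$r[1L], r, tolerance = 1e-12)
  expect_equal(mt$p[1L],
               2 * stats::pt(-abs(r) * sqrt(6 / (1 - r^2)), df = 6),
               tolerance = 1e-12)
  expect_equal(mt$p[1L], stats::cor.test(ms$eigengenes["ME1", ],
                                         trait)$p.value,
               tolerance = 1e-9)
  # eigengene proportional to the trait: |r| = 1
  xt <- matrix(rep(trait, each = 6), 6, 8,
               dimnames = dimnames(x)) +
    matrix(stats::rnorm(48, 0, 1e-6), 6, 8)
  mst <- eigengenes_and_merge(xt, rep(1L, 6))
  expect_gt(abs(module_trait_stats(mst, trait)$r[1L]), 0.999)
  # constant trait: NA with warning
  expect_warning(mtc <- module_trait_stats(ms, rep(1, 8)), "constant")
  expect_true(all(is.na(mtc$r)))
})

test_that("membership and significance identify planted hubs", {
  set.seed(56)
  trait <- rep(c(0, 1), each = 4)
  f <- as.numeric(scale(trait + stats::rnorm(8, 0, 0.2)))
  x <- rbind(
    hub = f + stats::rnorm(8, 0, 0.01),
    matrix(rep(f, each = 8), 8, 8) + matrix(stats::rnorm(64, 0, 0.6), 8),
    ortho = stats::residuals(stats::lm(stats::rnorm(8) ~ trait + f))
  )
  rownames(x) <- c("hub", paste0("m", 1:8), "ortho")
  colnames(x) <- paste0("S", 1:8)
  ms <- eigengenes_and_merge(x, c(rep(1L, 9), 0L))
  mm <- membership_significance_hubs(x, ms, trait,
                                     mm_cut = 0.8, ps_cut = 0.5)
  expect_equal(attr(mm, "hubs")[1L], "hub")
  expect_lt(abs(mm$ps[mm$feature_id == "ortho"]), 0.3)
  expect_false(mm$hub[mm$feature_id == "ortho"])
  expect_true(is.na(mm$mm[mm$feature_id == "ortho"]))
})

test_that("module recovery pipeline is invariant to orderings", {
  pr <- simulate_proteome(sim_config(n_proteins = 300L, n_modules = 2L,
                                     module_sizes = c(60L, 50L),
                                     latent_strength = 2, frac_de = 0,
                                     n_phosphosites = 10L, seed = 57L))
  x <- pr$matrix
  run <- function(m) {
    adj <- signed_adjacency(m, 8)
    detect_modules(1 - tom_similarity(adj), min_size = 30L,
                   similarity = adj)
  }
  base <- run(x)
  perm <- sample(nrow(x))
  shuffled <- run(x[perm, ])
  # same partition after undoing the permutation (labels may be renamed)
  skip_if_not_installed("mclust")
  expect_equal(mclust::adjustedRandIndex(base[rownames(x)],
                                         shuffled[rownames(x)]), 1)
  sperm <- sample(ncol(x))
  expect_equal(mclust::adjustedRandIndex(base, run(x[, sperm])), 1)
})

test_that("planted latent-factor modules are recovered end to end", {
  skip_if_not_installed("mclust")
  pr <- simulate_proteome(module_recovery_config(58L))
  res <- suppressWarnings(suppressMessages(
    build_coexpression(pr$matrix, pr$metadata$trait)
  ))
  truth <- pr$truth$module_labels
  expect_gte(mclust::adjustedRandIndex(res$modules$labels, truth), 0.9)
  # eigengenes track the generating factors; trait module ranks first
  mt <- res$trait_stats
  top <- mt$module[which.max(abs(mt$r))]
  det_in_mod1 <- names(which(truth == 1L))
  lab1 <- res$modules$labels[det_in_mod1]
  major <- as.integer(names(sort(table(lab1[lab1 > 0]),
                                 decreasing = TRUE))[1L])
  expect_equal(top, paste0("ME", major))
  for (m in 1:3) {
    memb <- names(which(truth == m))
    labm <- res$modules$labels[memb]
    det <- as.integer(names(sort(table(labm[labm > 0]),
                                 decreasing = TRUE))[1L])
    me <- res$modules$eigengenes[paste0("ME", det), ]
    expect_gte(abs(stats::cor(me, pr$truth$latent_factors[m, ])), 0.9)
  }
})
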