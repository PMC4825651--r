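# Flank windows, motif matrices, step table and flexibility profiles.

test_that("step table reproduces the printed anchors and RC symmetry", {
  st <- step_table()
  expect_equal(st["GC", "twist"], 36.1)
  expect_equal(st["GC", "slide"], 0.41)
  expect_equal(st["GG", "twist"], 32.9)
  expect_equal(st["GG", "slide"], -0.22)
  rc <- function(s) revcomp(s)
  for (s in rownames(st)) {
    s2 <- rc(s)
    for (p in c("twist", "roll", "rise", "slide"))
      expect_equal(st[s, p], st[s2, p])
    for (p in c("tilt", "shift"))
      expect_equal(st[s, p], -st[s2, p])
  }
})

test_that("TSD windows are 20+8+20 and point windows put the site at position 21", {
  g <- make_genome(c(c1 = 1000), gc = 0.5, seed = 131)
  gs <- as.character(g[["c1"]])
  # + strand TSD starting at 1-based 101 spans [81, 128]
  tsd <- make_sites("c1", 101, width = 8)
  fw <- extract_flank_windows(tsd, g, layout = "tsd")
  expect_equal(fw$width, 48L)
  expect_equal(nchar(fw$seq), 48L)
  expect_equal(fw$seq, substr(gs, 81, 128))
  expect_equal(substr(fw$seq, 21, 28), substr(gs, 101, 108))

  pt <- make_sites("c1", 301)
  fp <- extract_flank_windows(pt, g, layout = "point")
  expect_equal(nchar(fp$seq), 48L)
  expect_equal(fp$site_position, 21L)
  expect_equal(substr(fp$seq, 21, 21), substr(gs, 301, 301))
  expect_equal(fp$seq, substr(gs, 281, 328))

  # minus-strand point window: reverse complement mirrored about the point
  mn <- make_sites("c1", 301, strand = "-")
  fm <- extract_flank_windows(mn, g, layout = "point")
  expect_equal(fm$seq, revcomp(substr(gs, 274, 321)))
  expect_equal(substr(fm$seq, 21, 21), revcomp(substr(gs, 301, 301)))

  # minus-strand TSD window is the reverse complement of the plus window
  mt <- make_sites("c1", 101, width = 8, strand = "-")
  ft <- extract_flank_windows(mt, g, layout = "tsd")
  expect_equal(ft$seq, revcomp(substr(gs, 81, 128)))
})

test_that("out-of-bounds and N-containing windows are excluded and tallied", {
  g <- toy_genome(c(c1 = paste(c(rep("A", 100), "N", rep("A", 99)),
                               collapse = "")))
  s <- make_sites("c1", c(5, 95, 150))   # near edge / spans N / clean
  fw <- extract_flank_windows(s, g, layout = "point")
  expect_equal(length(fw$seq), 1L)
  expect_equal(fw$n_excluded, 2L)
  expect_error(extract_flank_windows(s, g, layout = "tsd"), "8-bp")
})

test_that("position matrices are probability-normalised with bounded bits", {
  w <- rep("ACGTACGTAC", 10)
  pm <- position_matrix(w)
  expect_true(all(abs(rowSums(pm$prob) - 1) < 1e-12))
  expect_equal(pm$bits, rep(2, 10))        # zero entropy
  mixed <- c("AAAA", "AAAA", "CCCC", "CCCC")
  pm2 <- position_matrix(mixed)
  expect_equal(pm2$bits, rep(1, 4))        # p = (1/2, 1/2)
  flat <- c("ACGT", "CGTA", "GTAC", "TACG")
  pm3 <- position_matrix(flat)
  expect_equal(pm3$bits, rep(0, 4))        # uniform
  expect_true(all(pm3$bits >= 0 & pm3$bits <= 2))
})

test_that("flexibility profiles reduce windows to per-position step means", {
  st <- step_table()
  homo <- rep(paste(rep("A", 48), collapse = ""), 5)
  prof <- flexibility_profile(homo, "twist")
  expect_equal(length(prof$exp), 47L)
  expect_equal(prof$exp, rep(st["AA", "twist"], 47))

  one <- "ACGTTGCAGT"
  steps <- sapply(1:9, function(i) substr(one, i, i + 1))
  for (p in c("twist", "slide", "tilt")) {
    prof1 <- flexibility_profile(one, p)
    expect_equal(prof1$exp, unname(st[steps, p]))
  }
})

test_that("duplicating every window leaves the profile unchanged", {
  g <- make_genome(c(c1 = 5000), gc = 0.4, seed = 141)
  set.seed(142)
  s <- make_sites("c1", sample(100:4900, 30))
  fw <- extract_flank_windows(s, g, layout = "point")
  a <- flexibility_profile(fw, "roll")$exp
  b <- flexibility_profile(c(fw$seq, fw$seq), "roll")$exp
  expect_identical(a, b)
})

test_that("window sets closed under reverse complement give (anti)symmetric profiles", {
  g <- make_genome(c(c1 = 20000), gc = 0.5, seed = 151)
  set.seed(152)
  s <- make_sites("c1", sample(100:19000, 100))
  fw <- extract_flank_windows(s, g, layout = "point")
  wset <- c(fw$seq, revcomp(fw$seq))
  for (p in c("twist", "roll", "rise", "slide")) {
    prof <- flexibility_profile(wset, p)$exp
    expect_equal(prof, rev(prof), tolerance = 1e-12)
  }
  for (p in c("tilt", "shift")) {
    prof <- flexibility_profile(wset, p)$exp
    expect_equal(prof, -rev(prof), tolerance = 1e-12)
  }
})

test_that("profile divergence is zero when experiment equals the null mean", {
  set.seed(161)
  g <- make_genome(c(c1 = 30000), gc = 0.5, seed = 162)
  ctrl <- uniform_controls(g, 50, n_sets = 40, site_len = 1,
                           pool_size = 5000, seed = 163)
  cw <- control_flank_windows(ctrl, g)
  prof <- flexibility_profile(cw[[1]], "twist", control_windows = cw)
  # experiment == one of the control replicates: |z| small
  d <- profile_divergence(prof)
  expect_true(all(is.finite(d$z)))
  expect_lt(max(abs(d$z)), 6)
  # experiment identical to the control mean: z exactly 0
  prof0 <- prof
  prof0$exp <- prof$ctrl_mean
  d0 <- profile_divergence(prof0)
  expect_equal(d0$z, rep(0, 47))
  expect_error(profile_divergence(
    flexibility_profile(cw[[1]], "twist", control_windows = cw[1:5])),
    ">= 30")
})

test_that("null per-position z-scores behave like a standard normal", {
  g <- make_genome(c(c1 = 50000), gc = 0.5, seed = 171)
  ctrl <- uniform_controls(g, 100, n_sets = 60, site_len = 1,
                           pool_size = 20000, seed = 172)
  cw <- control_flank_windows(ctrl, g)
  exp_w <- cw[[60]]
  prof <- flexibility_profile(exp_w, "twist", control_windows = cw[1:59])
  z <- profile_divergence(prof)$z
  expect_lt(abs(mean(z)), 1)
  expect_lt(sd(z), 2.5)
  expect_gt(sd(z), 0.4)
})
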