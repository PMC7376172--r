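test_that("window averages assign full-window means to center residues", {
  # constant series stays constant
  p <- window_average(rep(2.5, 20), 7)
  expect_true(all(p$values == 2.5))
  # 1..7 with window 7: single value 4 at center residue 4
  p2 <- window_average(1:7, 7)
  expect_equal(p2$values, 4)
  expect_equal(profile_residues(p2), 4L)
  # 140 residues, window 7: centers 4..137 (134 values)
  p3 <- window_average(rnorm(140), 7)
  expect_equal(range(profile_residues(p3)), c(4L, 137L))
  expect_length(p3$values, 134)
  expect_error(window_average(1:10, 4), "odd")
  expect_error(window_average(1:3, 7), "shorter")
  expect_error(window_average(c(1, NA, 3, 4, 5, 6, 7), 7), "NA")
})

test_that("window averaging is linear in the input series", {
  set.seed(1)
  x <- rnorm(30)
  y <- rnorm(30)
  lhs <- window_average(2 * x - 3 * y, 5)$values
  rhs <- 2 * window_average(x, 5)$values - 3 * window_average(y, 5)$values
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("propensity profiles are windowed lookups", {
  tab <- load_builtin_table()
  expect_equal(propensity_profile("VVVVVVV", tab, "E")$values, 1.87)
  pA <- propensity_profile(strrep("A", 20), tab, "H")
  expect_true(all(abs(pA$values - 1.41) < 1e-12))
  # brute-force recomputation oracle on a random sequence
  set.seed(5)
  s <- paste(sample(rownames(tab), 30, replace = TRUE), collapse = "")
  got <- propensity_profile(s, tab, "E")
  vals <- vapply(strsplit(s, "")[[1]], function(r) tab[r, "E"], numeric(1))
  want <- vapply(4:27, function(c) mean(vals[(c - 3):(c + 3)]), numeric(1))
  expect_equal(got$values, want, tolerance = 1e-12)
  # an undefined cell is an error naming the position
  partial <- compute_propensities(ss_dataset("AVAVLK", "HEHECC"))
  expect_error(propensity_profile("AVGAVLK", partial, "E"), "position 3")
})

test_that("hydropathy profiles follow the bundled side-chain scale", {
  expect_equal(hydropathy_profile(strrep("I", 9))$values,
               rep(1.82, 3), tolerance = 1e-12)
  # hand-computed alternating lysine/valine window means
  p <- hydropathy_profile("KVKVKVKVK")
  v <- c(K = -2.77, V = 1.30)
  vals <- v[c("K", "V", "K", "V", "K", "V", "K", "V", "K")]
  want <- vapply(4:6, function(c) mean(vals[(c - 3):(c + 3)]), numeric(1))
  expect_equal(p$values, unname(want), tolerance = 1e-12)
  expect_error(hydropathy_profile("AXA", scale = roseman_scale()), "missing")
})

test_that("chameleon calls are maximal runs of high-beta windows in helix/coil context", {
  cfg <- scan_config()
  tab <- load_builtin_table()
  # uniformly sub-threshold profile yields nothing
  low <- window_average(rep(0.5, 20), 7, metric = "PE")
  expect_equal(nrow(detect_chameleon_regions(low, strrep("H", 20), cfg)), 0L)
  # valine run inside alanine flanks, all-helix context
  s <- "AAAAVVVVVVVAAAA"
  prof <- propensity_profile(s, tab, "E", cfg)
  got <- detect_chameleon_regions(prof, strrep("H", nchar(s)), cfg)
  # brute-force scan over center residues
  res <- profile_residues(prof)
  ok <- prof$values > 1
  runs <- rle(ok)
  expect_equal(nrow(got), 1L)
  want_idx <- range(which(ok))
  expect_equal(c(got$start, got$end), res[want_idx])
  # strand context suppresses calls
  none <- detect_chameleon_regions(prof, strrep("E", nchar(s)), cfg)
  expect_equal(nrow(none), 0L)
  expect_error(detect_chameleon_regions(prof, "HHH", cfg), "cover")
})

test_that("region boundaries match an exhaustive scan on random profiles", {
  cfg <- scan_config()
  set.seed(99)
  for (rep in 1:100) {
    n <- sample(10:40, 1)
    vals <- rnorm(n, mean = 1, sd = 0.4)
    prof <- structure(list(start_residue = 4L, values = vals,
                           metric = "PE", window = 7L),
                      class = "ss_profile")
    ctx <- paste(sample(c("H", "C", "E"), n + 3, replace = TRUE),
                 collapse = "")
    got <- detect_chameleon_regions(prof, ctx, cfg)
    # exhaustive: walk every center, collect maximal qualifying runs
    res <- profile_residues(prof)
    ctxv <- strsplit(ctx, "")[[1]]
    ok <- vals > 1 & ctxv[res] %in% c("H", "C")
    want <- list()
    i <- 1
    while (i <= length(ok)) {
      if (ok[i]) {
        j <- i
        while (j < length(ok) && ok[j + 1]) j <- j + 1
        if (j - i + 1 >= cfg$min_region_len)
          want[[length(want) + 1]] <- c(res[i], res[j])
        i <- j + 1
      } else i <- i + 1
    }
    expect_equal(nrow(got), length(want))
    if (length(want) > 0) {
      expect_equal(got$start, vapply(want, function(x) x[1], numeric(1)))
      expect_equal(got$end, vapply(want, function(x) x[2], numeric(1)))
    }
  }
})

test_that("hydrophobic regions are above-zero runs, down to single residues", {
  cfg <- scan_config()
  neg <- structure(list(start_residue = 4L, values = rep(-1, 10),
                        metric = "hydropathy", window = 7L),
                   class = "ss_profile")
  expect_equal(nrow(detect_hydrophobic_regions(neg, cfg)), 0L)
  step <- structure(list(start_residue = 4L,
                         values = c(rep(-1, 5), rep(1, 5), rep(-1, 5)),
                         metric = "hydropathy", window = 7L),
                    class = "ss_profile")
  got <- detect_hydrophobic_regions(step, cfg)
  expect_equal(nrow(got), 1L)
  expect_equal(c(got$start, got$end), c(9L, 13L))
  expect_equal(got$score, 1)
})

test_that("region calls shift with the sequence frame", {
  vals <- c(rep(0, 4), rep(2, 5), rep(0, 4))
  base <- structure(list(start_residue = 4L, values = vals,
                         metric = "PE", window = 7L), class = "ss_profile")
  shifted <- base
  shifted$start_residue <- 9L
  cfg <- scan_config()
  ctx <- strrep("H", 40)
  a <- detect_chameleon_regions(base, ctx, cfg)
  b <- detect_chameleon_regions(shifted, ctx, cfg)
  expect_equal(b$start, a$start + 5L)
  expect_equal(b$end, a$end + 5L)
})

test_that("glycine-valine pair detection honours order and position", {
  expect_equal(find_gv_sites("KTKEGV")$start, 5L)
  expect_equal(find_gv_sites("KTKEGV")$end, 6L)
  expect_equal(nrow(find_gv_sites("AAAA")), 0L)
  both <- find_gv_sites("VGAGV", "both")
  expect_equal(both$start, c(1L, 4L))
  expect_equal(both$motif, c("VG", "GV"))
  expect_equal(nrow(find_gv_sites("VGAGV", "GV")), 1L)
  expect_equal(nrow(find_gv_sites("VGAGV", "VG")), 1L)
  expect_equal(nrow(find_gv_sites("V")), 0L)
})

test_that("valine-to-alanine scanning mutates exactly the given sites", {
  expect_equal(alanine_scan("GV", 2), "GA")
  expect_equal(alanine_scan("GVKV", integer(0)), "GVKV")
  expect_error(alanine_scan("GV", 1), "not valine")
  expect_error(alanine_scan("GV", 5), "out of range")
})

test_that("mutating valines never raises the windowed beta-propensity profile", {
  tab <- load_builtin_table()
  s <- alpha_synuclein_seq()
  gv <- find_gv_sites(s, "both")
  vsites <- ifelse(gv$motif == "GV", gv$end, gv$start)
  mut <- alanine_scan(s, vsites)
  wt_prof <- propensity_profile(s, tab, "E")
  mut_prof <- propensity_profile(mut, tab, "E")
  expect_true(all(mut_prof$values <= wt_prof$values + 1e-12))
  expect_true(any(mut_prof$values < wt_prof$values))
})

test_that("profile correlation returns Pearson r with a two-sided p-value", {
  mk <- function(v) structure(list(start_residue = 4L, values = v,
                                   metric = "x", window = 7L),
                              class = "ss_profile")
  set.seed(2)
  x <- rnorm(50)
  expect_equal(profile_correlation(mk(x), mk(x))$r, 1)
  expect_equal(profile_correlation(mk(x), mk(-x))$r, -1)
  expect_error(profile_correlation(mk(x), mk(rep(1, 50))), "zero-variance")
  expect_error(profile_correlation(mk(x), mk(rnorm(20))), "same residues")
  # sampling check: bivariate normal with rho = 0.6 at the profile length
  # used for a 140-residue chain
  set.seed(31)
  n <- 134
  a <- rnorm(n)
  b <- 0.6 * a + sqrt(1 - 0.36) * rnorm(n)
  r <- profile_correlation(mk(a), mk(b))$r
  expect_lt(abs(r - 0.6), 0.15)
})

test_that("region export declares its coordinate convention", {
  df <- data.frame(kind = "chameleon", start = 4L, end = 9L, score = 1.2)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_regions(df, f)
  expect_match(readLines(f, n = 1), "1-based inclusive")
  back <- read.table(f, sep = "\t", header = TRUE, comment.char = "#")
  expect_equal(back$start, 4L)
  write_regions(df, f, zero_based = TRUE)
  expect_match(readLines(f, n = 1), "0-based half-open")
  back0 <- read.table(f, sep = "\t", header = TRUE, comment.char = "#")
  expect_equal(back0$start, 3L)
})
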