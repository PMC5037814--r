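test_that("peak lists are read, sorted and validated", {
  p <- write_peaklist_fixture(data.frame(mz = c(1200, 1000),
                                         intensity = c(5, 10)))
  pl <- read_peaklist(p, mode = ion_mode("negative"), scale = "average")
  expect_s3_class(pl, "peaklist")
  expect_equal(nrow(pl$peaks), 2)
  expect_equal(pl$peaks$mz, c(1000, 1200))
  expect_equal(pl$scale, "average")
  expect_equal(pl$mode$polarity, "negative")

  expect_error(read_peaklist(write_peaklist_fixture(
    data.frame(mz = 1000, intensity = -1))), "non-negative")
  expect_error(read_peaklist(write_peaklist_fixture(
    data.frame(m = 1000, intensity = 1))), "mz")
  expect_error(peaklist(c(1000, 1000 + 1e-8), c(1, 1)), "duplicate")
  expect_error(peaklist(numeric(0), numeric(0)), "non-empty")
})

test_that("signal-to-noise estimation uses explicit noise or local medians", {
  pl <- peaklist(c(1000, 1010), c(25, 10), noise = c(10, 10))
  snr <- estimate_snr(pl)
  expect_equal(snr$peaks$snr, c(2.5, 1.0))

  # isolated tall peak among uniform background b = 4
  pl2 <- peaklist(c(990, 995, 1000, 1005, 1010), c(4, 4, 40, 4, 4))
  snr2 <- estimate_snr(pl2, window = 100)
  expect_equal(snr2$peaks$snr[3], 10)
  # background peak: local median includes the tall one but median resists it
  expect_equal(snr2$peaks$snr[1], 1)

  expect_error(estimate_snr(peaklist(1000, 5)), "single-peak")
})

test_that("compositions are assigned by expected mass with S/N acceptance", {
  pep <- "ACDEFGHIK"
  mode <- ion_mode("negative"); scale <- "monoisotopic"
  base <- peptide_neutral_mass(pep, "intact", scale)
  mz0 <- ion_mz(base, mode)
  mz2 <- ion_mz(base + modification_delta(mod_composition(2, 1, 0), scale),
                mode)
  pl <- peaklist(c(mz0, mz2), c(100, 50), noise = c(10, 10),
                 mode = mode, scale = scale)
  asg <- assign_compositions(pl, pep, tolerance = 1.0)
  expect_equal(nrow(asg), 2)
  expect_true(all(asg$accepted))
  expect_equal(asg$n_hexnac, c(0, 2))
  expect_equal(asg$n_hex, c(0, 1))
  expect_equal(asg$error, c(0, 0), tolerance = 1e-9)

  # sub-threshold S/N: assignment exists but is not accepted
  pl_low <- peaklist(c(mz0, mz2), c(100, 8), noise = c(10, 10),
                     mode = mode, scale = scale)
  asg_low <- assign_compositions(pl_low, pep, tolerance = 1.0,
                                 snr_threshold = 1.0)
  row2 <- asg_low[asg_low$n_hexnac == 2, ]
  expect_equal(nrow(row2), 1)
  expect_equal(row2$snr, 0.8)
  expect_false(row2$accepted)
  # S/N exactly at the threshold is rejected (strict inequality)
  pl_at <- peaklist(mz0, 10, noise = 10, mode = mode, scale = scale)
  expect_false(assign_compositions(pl_at, pep)$accepted)

  empty <- assign_compositions(pl, pep,
                               comp_space = default_comp_space(integer(0),
                                                               integer(0),
                                                               integer(0)))
  expect_equal(nrow(empty), 0)
})

test_that("each observed peak is used at most once and matching is anti-monotone in tolerance", {
  set.seed(21)
  pep <- "MKWVTFISLLK"
  mode <- ion_mode("positive"); scale <- "average"
  for (rep in 1:20) {
    n <- sample(5:25, 1)
    mz <- sort(runif(n, 2000, 4200))
    while (any(diff(mz) < 0.01)) mz <- sort(runif(n, 2000, 4200))
    pl <- peaklist(mz, runif(n, 1, 100), noise = rep(1, n),
                   mode = mode, scale = scale)
    tols <- c(0.3, 1.0, 3.0)
    sets <- lapply(tols, function(tol) {
      a <- assign_compositions(pl, pep, tolerance = tol)
      expect_true(anyDuplicated(a$observed_mz) == 0)
      expect_true(all(abs(a$error) <= tol))
      paste(a$n_hexnac, a$n_hex, a$n_phos)
    })
    expect_true(all(sets[[1]] %in% sets[[2]]))
    expect_true(all(sets[[2]] %in% sets[[3]]))
  }
})

test_that("ambiguous compositions with coincident expected masses are flagged", {
  pep <- "ACDEFGHIK"
  scale <- "monoisotopic"; mode <- ion_mode("positive")
  base <- peptide_neutral_mass(pep, "intact", scale)
  space <- data.frame(n_hexnac = c(1, 1), n_hex = c(0, 0), n_phos = c(0, 0))
  pl <- peaklist(ion_mz(base + modification_delta(mod_composition(1, 0, 0),
                                                  scale), mode),
                 100, noise = 10, mode = mode, scale = scale)
  asg <- assign_compositions(pl, pep, comp_space = space)
  expect_true(all(asg$ambiguous))
})

test_that("mass ladders are detected as maximal chains", {
  mode <- ion_mode("positive")
  pl <- peaklist(c(1000, 1162.1, 1324.3), c(10, 8, 5),
                 noise = rep(1, 3), mode = mode, scale = "average")
  lad <- detect_ladders(pl, steps = "hexose", tolerance = 0.5)
  expect_length(lad, 1)
  expect_equal(lad[[1]]$step, "hexose")
  expect_equal(lad[[1]]$base_peak_mz, 1000)
  expect_equal(lad[[1]]$member_mzs, c(1000, 1162.1, 1324.3))

  pl2 <- peaklist(c(1000, 1080.0), c(10, 5), noise = rep(1, 2),
                  mode = mode, scale = "average")
  lad2 <- detect_ladders(pl2, steps = "phosphoryl", tolerance = 0.5)
  expect_length(lad2, 1)
  expect_equal(lad2[[1]]$member_mzs, c(1000, 1080))

  pl3 <- peaklist(1000, 10, noise = 1, mode = mode, scale = "average")
  expect_length(detect_ladders(pl3, steps = "hexose", tolerance = 0.5), 0)
})

test_that("glycoform profiles are peak-height fractions with a major form", {
  pep <- "ACDEFGHIK"
  scale <- "monoisotopic"; mode <- ion_mode("negative")
  base <- peptide_neutral_mass(pep, "intact", scale)
  mzs <- vapply(list(c(0, 0, 0), c(2, 1, 0)), function(cc)
    ion_mz(base + modification_delta(mod_composition(cc[1], cc[2], cc[3]),
                                     scale), mode), numeric(1))
  pl <- peaklist(mzs, c(25, 75), noise = c(1, 1), mode = mode,
                 scale = scale)
  prof <- glycoform_profile(assign_compositions(pl, pep))
  expect_equal(sum(prof$table$relative_height), 1, tolerance = 1e-9)
  expect_equal(sort(prof$table$relative_height), c(0.25, 0.75))
  expect_equal(unclass(prof$major_form), c(n_hexnac = 2L, n_hex = 1L,
                                           n_phos = 0L),
               ignore_attr = TRUE)

  # single accepted assignment
  pl1 <- peaklist(mzs[1], 10, noise = 1, mode = mode, scale = scale)
  prof1 <- glycoform_profile(assign_compositions(pl1, pep))
  expect_equal(prof1$table$relative_height, 1)

  # nothing accepted -> rejection
  pl0 <- peaklist(mzs[1], 0.5, noise = 1, mode = mode, scale = scale)
  expect_error(glycoform_profile(assign_compositions(pl0, pep)),
               "accepted")
})

test_that("phosphoform summary reports which phospho counts are present", {
  pep <- "GGSSEE"
  scale <- "average"; mode <- ion_mode("positive")
  base <- peptide_neutral_mass(pep, "intact", scale)
  mzs <- vapply(0:2, function(p)
    ion_mz(base + modification_delta(mod_composition(0, 0, p), scale),
           mode), numeric(1))
  pl <- peaklist(mzs, c(50, 30, 20), noise = rep(1, 3), mode = mode,
                 scale = scale)
  ph <- phospho_summary(assign_compositions(pl, pep))
  expect_equal(ph$n_phos, 0:2)
  expect_equal(ph$fraction, c(0.5, 0.3, 0.2))
})
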