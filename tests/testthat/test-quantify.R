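test_that("mean intensity matches hand values and the pixel-loop oracle", {
  px <- matrix(7, 20, 20)
  mask <- matrix(FALSE, 20, 20); mask[3:8, 3:8] <- TRUE
  expect_identical(meanIntensity(px, mask), list(mean = 7, sd = 0, nPixels = 36L))
  px2 <- matrix(0, 16, 16); px2[1, 1:4] <- c(1, 2, 3, 4)
  m2 <- matrix(FALSE, 16, 16); m2[1, 1:4] <- TRUE
  r <- meanIntensity(px2, m2)
  expect_identical(r$mean, 2.5)
  expect_equal(r$sd, sqrt(1.25), tolerance = 1e-15) # population SD of 1..4
  expect_identical(r$nPixels, 4L)
  withr::local_seed(41)
  for (i in 1:10) {
    rim <- randomImageMask(32L, 32L)
    got <- meanIntensity(rim$px, rim$mask)
    want <- oracleMeanSD(rim$px, rim$mask)
    expect_identical(got$mean, want$mean) # integer sums: exact in doubles
    expect_equal(got$sd, want$sd, tolerance = 1e-13)
    expect_identical(got$nPixels, want$nPixels)
  }
  expect_error(meanIntensity(px, matrix(FALSE, 20, 20)), "empty-region")
})

test_that("hip normalization hits the reference level and is idempotent", {
  px <- matrix(10, 32, 32)
  hip <- matrix(FALSE, 32, 32); hip[20:25, 20:25] <- TRUE
  px[hip] <- 50
  res <- hipNormalize(NIRImage(px), hip, R = 100)
  expect_identical(res$normFactor, 2)
  expect_identical(mean(pixels(res$image)[hip]), 100)
  # already at R: factor 1, image unchanged
  res2 <- hipNormalize(res$image, hip, R = 100)
  expect_identical(res2$normFactor, 1)
  expect_identical(pixels(res2$image), pixels(res$image))
  # scaling then normalizing equals normalizing the original
  for (c in c(0.25, 3, 12)) {
    resC <- hipNormalize(NIRImage(px * c), hip, R = 100)
    expect_lt(max(abs(pixels(resC$image) - pixels(res$image))) /
                max(pixels(res$image)), 1e-12)
  }
  expect_error(hipNormalize(NIRImage(matrix(0, 32, 32)), hip), "normalization error")
})

test_that("autofluorescence estimation recovers the configured baseline", {
  # constant control after normalization -> A equals the constant
  px <- matrix(5, 32, 32)
  hip <- matrix(FALSE, 32, 32); hip[4:9, 4:9] <- TRUE
  body <- matrix(TRUE, 32, 32)
  expect_equal(estimateAutofluorescence(NIRImage(px), body, hip, R = 5,
                                        bodyErode = 0), 5)
  # phantom: A within 2% of A0 * (R / hip level), with noise, fixed seed
  tr <- smallTruth(seed = 63L)
  ctr <- generatePhantom(uninjected(tr), 0)
  g <- generatePhantom(tr, 1)
  hipM <- hipReferenceROI(g$regions)
  A <- estimateAutofluorescence(ctr$image, regionMask(g$regions, "body"), hipM,
                                R = 100)
  hipLevel <- tr@autofluorescence * tr@luminosity
  expect_equal(A, tr@autofluorescence * (100 / hipLevel), tolerance = 0.02)
  # missing control routes the user to the hip fallback
  expect_error(estimateAutofluorescence(ctr$image, body, NULL),
               "configuration error")
  # hip fallback inside biodistribution: A = R * hipAfFraction, flagged
  cht <- generateCohort(tr, 1, 1)
  tct <- biodistribution(cht, hipAfFraction = 1)
  expect_identical(tct@afSource, "hip_fallback")
  expect_identical(unique(measurements(tct)$autofluorescence), 100)
})

test_that("the SNR statistic follows its definition in both modes", {
  A <- 40
  px <- matrix(A, 32, 32)
  roi <- matrix(FALSE, 32, 32); roi[5:10, 5:10] <- TRUE
  bg <- matrix(FALSE, 32, 32); bg[20:21, 1:32] <- TRUE
  px[bg] <- rep(c(A - 2, A + 2), 32) # bg mean A, population SD exactly 2
  # an autofluorescence-only ROI scores 0 in both modes
  expect_equal(snr(px, roi, bg, A, "noise_sd"), 0)
  expect_equal(snr(px, roi, bg, A, "mean_ratio"), 0)
  # mean_roi = A + 10, sd_bg = 2 -> 5
  px[roi] <- A + 10
  expect_equal(snr(px, roi, bg, A, "noise_sd"), 5)
  # mean_ratio mode with a background above baseline
  px[bg] <- px[bg] + 4 # bg mean A + 4
  expect_equal(snr(px, roi, bg, A, "mean_ratio"), 10 / 4)
  # degenerate background
  px[bg] <- A + 1
  expect_error(snr(px, roi, bg, A, "noise_sd"), "degenerate-background")
  expect_error(snr(px, roi, roi, A), "disjoint")
})

test_that("SNR is invariant to global luminosity and negative values pass through", {
  tr <- smallTruth(seed = 77L)
  ctr <- generatePhantom(uninjected(tr), 0)
  g <- generatePhantom(tr, 1)
  base <- pipelineSNRs(g$image, g$regions, ctr$image)
  for (c in c(0.1, 10)) {
    scaled <- pipelineSNRs(NIRImage(pixels(g$image) * c), g$regions,
                           NIRImage(pixels(ctr$image) * c))
    expect_lt(max(abs(scaled - base) / abs(base)), 1e-9)
  }
  # a region dimmer than the autofluorescence scores negative, unclipped
  trDim <- smallTruth()
  trDim@regions[[1]]$cMax <- 0 # tumor carries no agent
  trDim@autofluorescence <- 20
  gD <- generatePhantom(noiseFree(trDim), 1)
  ctrD <- generatePhantom(uninjected(noiseFree(trDim)), 0)
  # tumor mean sits below the eroded-body baseline near the silhouette edge
  s <- pipelineSNRs(gD$image, gD$regions, ctrD$image)[["tumor"]]
  expect_true(is.finite(s))
  expect_lt(s, 1) # essentially zero contrast; sign is not forced positive
})

test_that("cohort SNR matches the noise-free expectation within 15%", {
  tr <- smallTruth(seed = 55L)
  nf <- noiseFree(tr)
  gRef <- generatePhantom(nf, 1)
  ctrRef <- generatePhantom(uninjected(nf), 0)
  ref <- pipelineSNRs(gRef$image, gRef$regions, ctrRef$image)[["tumor"]]
  cht <- generateCohort(tr, 5, 1, seed = 505L)
  ctr <- generatePhantom(uninjected(tr), 0)
  tct <- biodistribution(cht, rois = "tumor",
                         control = list(image = ctr$image, regions = ctr$regions))
  expect_equal(cohortSummary(tct)$mean_snr, ref, tolerance = 0.15)
})

test_that("biodistribution assembles counts, rankings, and drop logging", {
  tr <- smallTruth(seed = 99L)
  cht <- generateCohort(tr, 5, c(1, 2, 4), seed = 9L)
  ctr <- generatePhantom(uninjected(tr), 0)
  tct <- biodistribution(cht, control = list(image = ctr$image,
                                             regions = ctr$regions))
  meas <- measurements(tct)
  # 5 subjects x 3 timepoints x 2 quantified regions
  expect_identical(nrow(meas), 30L)
  summ <- cohortSummary(tct)
  expect_identical(nrow(summ), 6L)
  expect_true(all(summ$n == 5L))
  # tumor outranks liver at every timepoint
  for (t in c(1, 2, 4))
    expect_gt(summ$mean_snr[summ$roi_name == "tumor" & summ$timepoint_h == t],
              summ$mean_snr[summ$roi_name == "liver" & summ$timepoint_h == t])
  # sample SD across subjects (error-bar convention)
  g1 <- meas$snr[meas$roi_name == "tumor" & meas$timepoint_h == 1]
  expect_equal(summ$sd_snr[summ$roi_name == "tumor" & summ$timepoint_h == 1],
               sd(g1))
  # a missing region is dropped with a reason, not an error
  tct2 <- biodistribution(cht, rois = c("tumor", "muscle"),
                          control = list(image = ctr$image, regions = ctr$regions))
  expect_identical(nrow(measurements(tct2)), 15L)
  expect_identical(nrow(droppedRows(tct2)), 15L)
  expect_match(droppedRows(tct2)$reason[1], "muscle")
})

test_that("noise-free SNR rises strictly with tumor amplitude and modes agree on ranks", {
  # strict monotonicity on the noise-free path
  snrs <- vapply(c(150, 300, 600), function(a) {
    tr <- noiseFree(smallTruth())
    tr@regions[[1]]$cMax <- a
    g <- generatePhantom(tr, 1)
    ctr <- generatePhantom(uninjected(tr), 0)
    pipelineSNRs(g$image, g$regions, ctr$image)[["tumor"]]
  }, numeric(1))
  expect_true(all(diff(snrs) > 0))

  # rank agreement between noise_sd and mean_ratio modes on a symmetric
  # noise-free family: equal-geometry discs, each with an identical
  # fixed-amplitude scatter companion so every annulus sees the same
  # structural background
  regions <- list()
  amps <- c(30, 60, 120, 240)
  centers <- list(c(30, 40), c(30, 120), c(90, 40), c(90, 120))
  for (i in seq_along(amps)) {
    regions[[length(regions) + 1L]] <-
      phantomRegion(paste0("roi", i), "disc", center = centers[[i]], radius = 6,
                    cMax = amps[i], kIn = 1e3, kOut = 0)
    regions[[length(regions) + 1L]] <-
      phantomRegion(paste0("companion", i), "disc",
                    center = centers[[i]] + c(0, 14), radius = 4,
                    cMax = 80, kIn = 1e3, kOut = 0)
  }
  regions[[length(regions) + 1L]] <-
    phantomRegion("hip_ref", "disc", center = c(60, 80), radius = 6, cMax = 0)
  tr <- PhantomTruth(imageShape = c(120L, 160L), bodyCenter = c(60, 80),
                     bodySemiaxes = c(55, 75), regions = regions,
                     poissonGain = 0, readSigma = 0, seed = 5L)
  g <- generatePhantom(tr, 1)
  ctr <- generatePhantom(uninjected(tr), 0)
  s1 <- pipelineSNRs(g$image, g$regions, ctr$image, mode = "noise_sd")
  s2 <- pipelineSNRs(g$image, g$regions, ctr$image, mode = "mean_ratio")
  keep <- paste0("roi", seq_along(amps))
  expect_identical(cor(rank(s1[keep]), rank(s2[keep])), 1)
})
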