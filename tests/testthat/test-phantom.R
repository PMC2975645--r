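test_that("uptake kinetics obey the closed form and its limits", {
  # no uptake at injection, for any rates
  for (ki in c(0.1, 1, 3)) for (ko in c(0, 0.5))
    expect_identical(uptakeKinetics(10, ki, ko, 0), 0)
  # instant uptake, no washout -> plateau at cMax
  expect_equal(uptakeKinetics(10, 1e9, 0, 1), 10)
  # frozen closed-form values for the default tumor rates
  expect_equal(uptakeKinetics(10, 3, 0.02, 1), 9.313967, tolerance = 1e-6)
  expect_equal(uptakeKinetics(10, 3, 0.02, 4), 9.231107, tolerance = 1e-6)
  # the 1-4 h plateau regime: values within 10% of each other
  u <- uptakeKinetics(10, 3, 0.02, c(1, 4))
  expect_lt(abs(u[2] - u[1]) / u[1], 0.10)
  # bounded by cMax everywhere
  expect_true(all(uptakeKinetics(10, 3, 0.02, seq(0, 24, 0.5)) <= 10))
  expect_error(uptakeKinetics(10, -1, 0, 1), "must be >= 0")
  expect_error(uptakeKinetics(10, 1, 0, -2), "must be >= 0")
})

test_that("degenerate phantoms render exactly as constructed", {
  # all amplitudes zero, A0 = 0, noise off -> all-zero image
  tr <- noiseFree(uninjected(smallTruth()))
  tr@autofluorescence <- 0
  g <- generatePhantom(tr, 1)
  expect_true(all(pixels(g$image) == 0))
  # flat autofluorescence: every body pixel 5 * L, outside-body 0 (PSF off)
  tr2 <- noiseFree(uninjected(smallTruth()))
  tr2@autofluorescence <- 5
  tr2@luminosity <- 2
  tr2@psfSigma <- 0
  g2 <- generatePhantom(tr2, 1)
  body <- regionMask(g2$regions, "body")
  expect_true(all(pixels(g2$image)[body] == 10))
  expect_true(all(pixels(g2$image)[!body] == 0))
})

test_that("phantom generation is deterministic and tumor outshines liver", {
  tr <- PhantomTruth(seed = 42L)
  g1 <- generatePhantom(tr, 1)
  g2 <- generatePhantom(tr, 1)
  expect_identical(pixels(g1$image), pixels(g2$image))
  expect_identical(labelMatrix(g1$regions), labelMatrix(g2$regions))
  px <- pixels(g1$image)
  expect_gt(mean(px[regionMask(g1$regions, "tumor")]),
            mean(px[regionMask(g1$regions, "liver")]))
})

test_that("noise-free images equal a direct-convolution oracle", {
  tr <- PhantomTruth(
    imageShape = c(32L, 32L), bodyCenter = c(16, 16), bodySemiaxes = c(12, 14),
    regions = list(phantomRegion("tumor", "disc", center = c(12, 20), radius = 4,
                                 cMax = 50, kIn = 3, kOut = 0.02)),
    autofluorescence = 8, psfSigma = 1.2, poissonGain = 0, readSigma = 0)
  g <- generatePhantom(tr, 1)
  # rebuild the pre-blur field and convolve by brute force
  body <- nirquant:::ellipseMask(c(32L, 32L), c(16, 16), c(12, 14))
  tum <- nirquant:::discMask(c(32L, 32L), c(12, 20), 4)
  pre <- 8 * body + uptakeKinetics(50, 3, 0.02, 1) * tum
  ref <- oracleGaussBlur(pre, 1.2)
  expect_lt(max(abs(pixels(g$image) - ref)) / max(ref), 1e-9)
})

test_that("the PSF conserves total intensity (energy accounting)", {
  tr <- noiseFree(PhantomTruth())
  blurred <- nirquant:::phantomCleanImage(tr, 1)
  tr0 <- tr; tr0@psfSigma <- 0
  pre <- nirquant:::phantomCleanImage(tr0, 1)
  expect_lt(abs(sum(blurred) - sum(pre)) / sum(pre), 0.001)
})

test_that("tumor-mask mean strictly increases with configured amplitude", {
  means <- vapply(c(100, 200, 400), function(a) {
    tr <- noiseFree(smallTruth())
    tr@regions[[1]]$cMax <- a
    g <- generatePhantom(tr, 1)
    mean(pixels(g$image)[regionMask(g$regions, "tumor")])
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("phantom geometry invariants are enforced", {
  expect_error(
    PhantomTruth(imageShape = c(64L, 64L), bodyCenter = c(32, 32),
                 bodySemiaxes = c(20, 20),
                 regions = list(phantomRegion("tumor", "disc",
                                              center = c(32, 50), radius = 8,
                                              cMax = 10))),
    "outside the body")
  tr <- smallTruth()
  tr@autofluorescence <- -1
  expect_error(nirquant:::validatePhantomTruth(tr), "must be >= 0")
})

test_that("cohorts have one image per subject per timepoint, reproducibly", {
  tr <- smallTruth()
  cht <- generateCohort(tr, 5, c(1, 2, 4), seed = 7L)
  expect_length(cht, 15L)
  expect_identical(sort(unique(vapply(cht, `[[`, character(1), "subject_id"))),
                   sprintf("S%02d", 1:5))
  # same seed twice -> byte-identical collections
  cht2 <- generateCohort(tr, 5, c(1, 2, 4), seed = 7L)
  expect_identical(lapply(cht, function(r) pixels(r$image)),
                   lapply(cht2, function(r) pixels(r$image)))
  # a subject's geometry is shared across timepoints
  expect_identical(labelMatrix(cht[[1]]$regions), labelMatrix(cht[[3]]$regions))
  # single subject, single timepoint reduces to generatePhantom on the
  # derived sub-seeded truth
  one <- generateCohort(tr, 1, 1, seed = 7L)
  trS <- nirquant:::jitterTruth(tr, nirquant:::deriveSeed(7L, 1L))
  trS@seed <- nirquant:::deriveSeed(7L, 1L, 999L)
  expect_identical(pixels(one[[1]]$image), pixels(generatePhantom(trS, 1)$image))
})

test_that("ex vivo lung phantom realizes its stage constructions", {
  lt <- LungPhantomTruth(nodeCount = 8L)
  # noise-free localized: rim pixels sit exactly at reduced diffuse + rim
  ltNF <- lt; ltNF@poissonGain <- 0; ltNF@readSigma <- 0
  gl <- generateLungExVivo(ltNF, "localized")
  px <- pixels(gl$image)
  rim <- Reduce(`|`, lapply(grep("^rim_", regionNames(gl$regions), value = TRUE),
                            regionMask, x = gl$regions))
  expect_equal(mean(px[rim]), 30 * 0.3 + 60, tolerance = 1e-12)
  # nodes (with rims) lie inside the lung silhouette
  lungAll <- labelMatrix(gl$regions) > 0L
  lung <- nirquant:::lungSilhouette(lt)
  expect_true(all(lungAll == lung))
  # CV over the lung is strictly larger in the localized stage
  gd <- generateLungExVivo(lt, "diffuse")
  gl2 <- generateLungExVivo(lt, "localized")
  cv <- function(g) {
    v <- pixels(g$image)[labelMatrix(g$regions) > 0L]
    sd(v) / mean(v)
  }
  expect_gt(cv(gl2), cv(gd))
  # no nodes: localized is just the reduced diffuse level
  lt0 <- LungPhantomTruth(nodeCount = 0L, poissonGain = 0, readSigma = 0)
  g0l <- generateLungExVivo(lt0, "localized")
  g0d <- generateLungExVivo(lt0, "diffuse")
  m <- labelMatrix(g0d$regions) > 0L
  expect_equal(mean(pixels(g0l$image)[m]) / mean(pixels(g0d$image)[m]), 0.3,
               tolerance = 1e-12)
  # infeasible placement is a geometry error
  expect_error(
    generateLungExVivo(LungPhantomTruth(imageShape = c(24L, 24L),
                                        lobeCenters = rbind(c(12, 9), c(12, 15)),
                                        lobeSemiaxes = c(8, 5),
                                        nodeCount = 40L), "localized"),
    "feasible")
})
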