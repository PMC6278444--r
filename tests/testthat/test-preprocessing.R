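# Reference values computed with an independent wavelet implementation
# (PyWavelets 1.9, db7, mode='symmetric') for x = (1:20)^1.5.
pywt_db7_ca <- c(
  47.633084449723746, 34.61999079850934, 23.00966757718297,
  13.311069601158296, 4.989159328617448, 1.3386607232008605,
  5.848424925048696, 13.8254933171396, 23.82105868807903,
  35.48379503328442, 48.60662895520199, 62.97805003631983,
  78.88567126916571, 94.66653229401335, 115.03330740316629,
  126.31254477647195)
pywt_db7_cd <- c(
  0.2033439753458012, -0.35155429304348096, 0.20932284758398598,
  -0.060510954186860345, -0.0027982915029941776, 0.003694782418720231,
  0.00011431044023870791, 2.8900381388534575e-05, 1.0146381412625381e-05,
  4.289749843335196e-06, -1.1071918371807459, 1.9014382044673626,
  -1.1219990101354438, 0.34864377731927404, -0.0014515240543467728,
  -0.01944646651993336)
pywt_db7_smooth1 <- c(
  1.1362459284033726, 2.5536431368648382, 5.22395147093703,
  8.133623997613231, 11.124839236472368, 14.66977635203238,
  18.546387761058895, 22.62014124231098, 26.99978896457283,
  31.627232774132953, 36.48116265458123, 41.55226470530208,
  46.8533384562745, 52.45122505509507, 58.21586268289168,
  63.83403413141931, 69.67271279118644, 76.70950590684087,
  83.86144168191564, 88.26855100419812)

test_that("db7 analysis/synthesis agrees with an independent implementation", {
  x <- (1:20)^1.5
  s <- hsichem:::dwt_step(x)
  expect_equal(s$a, pywt_db7_ca, tolerance = 1e-12)
  expect_equal(s$d, pywt_db7_cd, tolerance = 1e-12)
  expect_equal(wt_smooth(x, level = 1L), pywt_db7_smooth1,
               tolerance = 1e-10)
  # perfect reconstruction when details are kept
  expect_equal(hsichem:::idwt_step(s$a, s$d, 20L), x, tolerance = 1e-10)
})

test_that("wavelet smoothing contracts: shape, constants, linearity, denoising", {
  expect_length(wt_smooth(rnorm(200)), 200L)
  expect_lt(max(abs(wt_smooth(rep(0.37, 200)) - 0.37)), 1e-8)

  # linearity of the zero-detail reconstruction
  hsichem:::with_seed(8L, {
    x <- rnorm(100); y <- rnorm(100)
    expect_lt(max(abs(wt_smooth(2 * x - 3 * y) -
                        (2 * wt_smooth(x) - 3 * wt_smooth(y)))), 1e-8)
  })

  # Monte-Carlo: smoothing a noisy signature moves it closer to the truth
  wl <- seq(975, 1646, length.out = 200)
  s <- make_signature(default_signatures()$A, wl)
  rmse <- function(a, b) sqrt(mean((a - b)^2))
  wins <- hsichem:::with_seed(42L, {
    vapply(1:100, function(i) {
      noisy <- s + rnorm(200, 0, 0.01)
      rmse(wt_smooth(noisy), s) < rmse(noisy, s)
    }, logical(1))
  })
  expect_gte(mean(wins), 0.99)

  expect_error(wt_smooth(rnorm(10)), "short")
})

test_that("SNV: canonical example, affine invariance, zero-variance error", {
  expect_equal(snv(c(1, 2, 3)), c(-1, 0, 1))
  hsichem:::with_seed(3L, {
    x <- rnorm(50)
    expect_equal(snv(3.2 * x + 7), snv(x), tolerance = 1e-10)
  })
  expect_error(snv(rep(1, 10)), "zero-variance")
})

test_that("preprocessing advances the stage and normalizes every row", {
  sc <- generate_scene(tiny_scene_config(seed = 21L))
  corr <- correct_reflectance(sc$raw, sc$refs)
  tab <- extract_pixel_spectra(corr, label_objects(segment_background(corr)),
                               "s21", "A", "Grade2")
  pp <- preprocess_pixels(tab)
  expect_identical(pp$stage, "wt+snv")
  expect_lt(max(abs(rowMeans(pp$spectra))), 1e-10)
  expect_lt(max(abs(apply(pp$spectra, 1, sd) - 1)), 1e-10)
  expect_identical(pp$meta, tab$meta)
  expect_error(preprocess_pixels(pp), "forward")

  # identical input rows stay identical after preprocessing
  dup <- pixel_spectra(tab$spectra[c(1, 1, 1), ], tab$meta[c(1, 1, 1), ],
                       tab$wavelengths, stage = "raw")
  ppd <- preprocess_pixels(dup)
  expect_equal(ppd$spectra[1, ], ppd$spectra[3, ])
})

test_that("scatter-corrupted pixels become more alike after preprocessing", {
  # strong scatter, no band noise: SNV should remove nearly all
  # between-pixel spread inside an object
  cfg <- tiny_scene_config(seed = 31L, scatter_gain_sd = 0.15,
                           scatter_offset_sd = 0.03, noise_sd = 0)
  sc <- generate_scene(cfg)
  corr <- correct_reflectance(sc$raw, sc$refs)
  tab <- extract_pixel_spectra(corr, label_objects(segment_background(corr)),
                               "s31", "A", "Grade2")
  pp <- preprocess_pixels(tab)
  rows <- which(tab$meta$object_id == 1L)
  # relative between-pixel spread within one object: raw spectra differ by
  # per-pixel gain/offset; after wt+snv they should be nearly identical
  rel_spread <- function(M) mean(apply(M, 2, sd)) / sd(as.vector(M))
  expect_lt(rel_spread(pp$spectra[rows, ]),
            0.1 * rel_spread(tab$spectra[rows, ]))
})

test_that("object averaging: means, permutation invariance, counts", {
  wl <- tiny_axis(16L)
  sp <- rbind(rep(0, 16), rep(2, 16), rep(5, 16))
  meta <- data.frame(scene_id = "s", object_id = c(1L, 1L, 2L),
                     class = "A", grade = "Grade2")
  tab <- pixel_spectra(sp, meta, wl, stage = "wt+snv")
  ob <- average_by_object(tab)
  expect_equal(nrow(ob$spectra), 2L)
  expect_equal(as.vector(ob$spectra[1, ]), rep(1, 16))   # mean of 0 and 2
  expect_equal(as.vector(ob$spectra[2, ]), rep(5, 16))   # single pixel
  expect_equal(ob$meta$n_pixels, c(2L, 1L))

  # permuting pixel rows within objects does not change the averages
  perm <- c(2L, 3L, 1L)
  tab2 <- pixel_spectra(sp[perm, ], meta[perm, ], wl, stage = "wt+snv")
  ob2 <- average_by_object(tab2)
  expect_equal(ob2$spectra[order(ob2$meta$object_id), ],
               ob$spectra[order(ob$meta$object_id), ], ignore_attr = TRUE)

  expect_error(average_by_object(
    pixel_spectra(sp, meta, wl, stage = "raw")), "wt\\+snv")
})
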