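test_that("intensity profiles track the underlying image", {
  ## constant image: flat profile, sd 0
  img <- matrix(40, 200, 200)    # 200 x 200 px at 0.01 mm = 2 x 2 mm
  path <- cbind(1, seq(0.2, 1.8, length.out = 2))
  p <- extractProfile(img, 0.01, path, step = 15, nLateral = 6)
  expect_true(all(p@mean == 40))
  expect_true(all(p@sd == 0))
  expect_true(all(p@n == 6L))
  ## positions advance in 15 um steps from the pial end
  expect_equal(diff(p@positions), rep(15, length(p@positions) - 1))
  ## image linear in depth: profile linear in position (constant increments)
  depth <- matrix(rep(seq_len(200), each = 200), 200, 200)  # varies along y
  p2 <- extractProfile(depth, 0.01, path, step = 15, nLateral = 4)
  incr <- diff(p2@mean)
  expect_lt(diff(range(incr)), 1e-9 * max(abs(p2@mean)))
  ## a path exiting the image is an error
  expect_error(extractProfile(img, 0.01, cbind(1, c(0.5, 3.5)), 15, 6),
               class = "corticomap_path_outside_image")
})

test_that("profile through a phantom section is darkest at the true band", {
  ## deep-band phantom: myelin peak at depth fraction 0.25 from the white
  ## surface, i.e. in the deep third of cortex
  spec <- testSpec(sheetTilt = 0, profilePeakDepth = 0.25)
  ph <- makePhantom(spec)
  hh <- renderHistology(ph$surface, ph$truth, spec, spacing = 1,
                        pixelSize = 0.05)
  mid <- which.min(abs(hh$positions - 10))
  img <- hh$series@images[[mid]]
  ## pial-to-white path at the patch centre (x = 10)
  zw <- spec@thickness + 0.5   # image z of slab midline (z0 = -(t + 0.5))
  path <- cbind(10, c(zw + 1, zw - 1))   # pial (z = +1) down to white (-1)
  p <- extractProfile(img, 0.05, path, step = 15, nLateral = 6)
  imin <- which.min(p@mean)
  relDepthFromPial <- p@positions[imin] / max(p@positions)
  ## the dark band sits in the deep third, at 1 - 0.25 of the depth
  expect_gt(relDepthFromPial, 2 / 3)
  expect_lt(abs(relDepthFromPial - 0.75), 0.1)
})

test_that("robust smoothing reproduces quadratics and shrugs off outliers", {
  x <- seq(0, 600, by = 15)
  quad <- 5 + 0.02 * x - 3e-5 * x^2
  prof <- new("IntensityProfile", positions = x, mean = quad,
              sd = rep(0, length(x)), n = rep(6L, length(x)))
  sm <- smoothProfile(prof, span = 0.5)
  expect_equal(sm@mean, quad, tolerance = 1e-6)
  ## constant profile unchanged
  cst <- new("IntensityProfile", positions = x, mean = rep(2, length(x)),
             sd = rep(0, length(x)), n = rep(6L, length(x)))
  expect_equal(smoothProfile(cst)@mean, rep(2, length(x)), tolerance = 1e-9)
  ## one gross outlier on a linear trend: smoothed value stays near the
  ## trend (robust bisquare downweighting)
  lin <- 10 + 0.05 * x
  dirty <- lin; k <- 21; dirty[k] <- dirty[k] + 100
  profd <- new("IntensityProfile", positions = x, mean = dirty,
               sd = rep(0, length(x)), n = rep(6L, length(x)))
  smd <- smoothProfile(profd, span = 0.4)
  expect_lt(abs(smd@mean[k] - lin[k]) / lin[k], 0.05)
  expect_error(smoothProfile(new("IntensityProfile", positions = x[1:4],
                                 mean = lin[1:4], sd = rep(0, 4),
                                 n = rep(6L, 4))),
               class = "corticomap_too_few_points")
})

test_that("profile comparison reproduces hand-computed KS statistics", {
  mkp <- function(v) new("IntensityProfile",
                         positions = seq_along(v) * 15, mean = v,
                         sd = rep(0, length(v)), n = rep(6L, length(v)))
  expect_equal(compareProfiles(mkp(c(1, 2, 3)), mkp(c(1, 2, 3)))$D, 0)
  expect_equal(compareProfiles(mkp(c(1, 2, 3)), mkp(c(4, 5, 6)))$D, 1)
  r <- compareProfiles(mkp(c(1, 2, 3, 4)), mkp(c(2, 3, 4, 5)))
  expect_equal(r$D, 0.25)
  expect_error(compareProfiles(mkp(1), mkp(c(1, 2))),
               class = "corticomap_too_few_points")
})

test_that("KS statistic matches a brute-force ECDF oracle", {
  set.seed(14)
  mkp <- function(v) new("IntensityProfile",
                         positions = seq_along(v) * 15, mean = v,
                         sd = rep(0, length(v)), n = rep(6L, length(v)))
  for (i in 1:500) {
    a <- round(rnorm(sample(3:12, 1)), 2)
    b <- round(rnorm(sample(3:12, 1), sample(c(0, 1), 1)), 2)
    expect_equal(compareProfiles(mkp(a), mkp(b))$D, oracleKS(a, b),
                 tolerance = 1e-12)
  }
})

test_that("section myelin length measures contiguous dark runs", {
  ## constructed section: 10 x 2 mm image at 0.01 mm; dark deep band under
  ## two pial segments: 2 mm and 1 mm runs
  px <- 0.01
  img <- matrix(200, 1000, 200)
  dark <- function(x0, x1) {
    cols <- 40:80   # deep band rows (z = 0.4 - 0.8 mm)
    img[(x0 / px):(x1 / px), cols] <<- 20
  }
  dark(2, 4); dark(6, 7)
  pial <- cbind(c(0.2, 9.8), 1.9)   # straight pial trace at z = 1.9 mm
  white <- cbind(c(0.2, 9.8), 0.1)  # white trace at z = 0.1
  len <- sectionMyelinLength(img, px, 100, pial, white, deepFraction = 0.7)
  runs <- attr(len, "runs")
  expect_equal(nrow(runs), 2)
  expect_equal(sort(runs$length), c(1, 2), tolerance = 0.02)
  expect_equal(as.numeric(len), 3, tolerance = 0.03)
  ## nothing strictly below the threshold: zero length
  none <- sectionMyelinLength(img, px, 20, pial, white)
  expect_equal(as.numeric(none), 0)
  ## threshold must lie within the image range
  expect_error(sectionMyelinLength(img, px, 500, pial, white),
               class = "corticomap_threshold_out_of_range")
})

test_that("phantom section lengths recover the analytic chords", {
  spec <- testSpec(sheetTilt = 0)
  ph <- makePhantom(spec)
  hh <- renderHistology(ph$surface, ph$truth, spec, spacing = 1,
                        pixelSize = 0.05)
  lens <- seriesMyelinLengths(hh$series, stainThresholdFor(spec),
                              hh$pialTrace, hh$whiteTrace)
  expect_equal(lens, hh$trueLengths, tolerance = 0.05)
})

test_that("trapezoid aggregation matches hand computations", {
  expect_equal(aggregateArea(c(2, 2, 2), 0.5), 2)
  expect_equal(aggregateArea(c(0, 4, 0), 1), 4)
  ## single nonzero section padded with zero neighbours: length x spacing
  expect_equal(aggregateArea(c(0, 3, 0), 2), 6)
  expect_error(aggregateArea(3, 1), class = "corticomap_too_few_sections")
  ## linear in lengths and spacing
  l <- c(0, 1, 3, 2, 0)
  expect_equal(aggregateArea(2 * l, 1), 2 * aggregateArea(l, 1))
  expect_equal(aggregateArea(l, 2), 2 * aggregateArea(l, 1))
  ## optional thickness end caps
  expect_equal(aggregateArea(c(2, 2), 1, thickness = 500, endCaps = TRUE),
               2 + 0.5 * 2)
})

test_that("halving the spacing barely changes a smooth series' area", {
  smoothLen <- function(d) 8 * exp(-d^2 / 8)
  a1 <- aggregateArea(smoothLen(seq(-5, 5, by = 1)), 1)
  a05 <- aggregateArea(smoothLen(seq(-5, 5, by = 0.5)), 0.5)
  expect_lt(abs(a1 - a05) / a05, 0.01)
})

test_that("area summaries reproduce the printed table", {
  tab <- macaqueAreaTable()
  s <- summarizeAreas(tab[-1], pool = list(mriBoth = c("mriLh", "mriRh")))
  get <- function(col) s[s$column == col, ]
  expect_equal(round(get("mriLh")$mean, 1), 83.6)
  expect_equal(round(get("mriLh")$sd, 1), 12.4)
  expect_equal(round(get("histLh")$mean, 1), 78.0)
  expect_equal(round(get("histLh")$sd, 1), 10.6)
  expect_equal(round(get("mriRh")$mean, 1), 81.2)
  expect_equal(round(get("mriRh")$sd, 1), 4.5)
  expect_equal(get("mriBoth")$n, 10)
  expect_equal(round(get("mriBoth")$mean, 1), 82.4)
  expect_equal(round(get("mriBoth")$sd, 1), 8.9)
  ## a single-value column reports its value with a missing (not zero) sd
  expect_equal(get("histRh")$mean, 65.1)
  expect_true(is.na(get("histRh")$sd))
  expect_error(summarizeAreas(data.frame(x = NA_real_)),
               class = "corticomap_empty_group")
})

test_that("method agreement reports Pearson r over complete pairs", {
  ## perfectly (anti-)proportional pairs
  expect_equal(methodAgreement(c(1, 2, 3), c(2, 4, 6))$r, 1)
  expect_equal(methodAgreement(c(1, 2, 3), c(-2, -4, -6))$r, -1)
  ## the four complete left-hemisphere pairs of the printed table
  tab <- macaqueAreaTable()
  expect_message(r <- methodAgreement(tab$mriLh, tab$histLh), "dropping")
  expect_equal(r$n, 4)
  expect_equal(round(r$r, 3), 0.996)
  expect_equal(r$r, oraclePearson(c(71.4, 94.7, 88.5, 94.1),
                                  c(66, 90.3, 81.6, 89.3)))
  expect_lt(r$p, 0.05)
  expect_error(methodAgreement(c(1, 2), c(1, 2)),
               class = "corticomap_too_few_pairs")
  expect_error(methodAgreement(c(1, 1, 1), c(1, 2, 3)),
               class = "corticomap_zero_variance")
})

test_that("Pearson r matches a brute-force oracle on random cases", {
  set.seed(15)
  for (i in 1:500) {
    n <- sample(3:12, 1)
    x <- rnorm(n); y <- rnorm(n) + 0.5 * x
    expect_equal(methodAgreement(x, y)$r, oraclePearson(x, y),
                 tolerance = 1e-12)
  }
})
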