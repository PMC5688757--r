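blank_projection <- function(ny = 40, nx = 40, px = 0.5) {
  projection2d(matrix(0, ny, nx), "zo1", px, c(0, 0))
}

test_that("one seed on a blank boundary yields a single region covering the image", {
  pr <- blank_projection()
  profs <- segment_profiles(pr, cbind(5, 5))
  expect_equal(nrow(profs), 1)
  expect_equal(profs$area_um2, 40 * 40 * 0.25)
})

test_that("two seeds split by a bright wall meet at the wall", {
  ny <- 41; nx <- 41; px <- 1
  img <- matrix(0, ny, nx)
  img[, 21] <- 1  # vertical wall at x = 20.5
  pr <- projection2d(img, "zo1", px, c(0, 0))
  profs <- segment_profiles(pr, rbind(c(10, 20), c(30, 20)))
  lab <- attr(profs, "label_image")
  expect_equal(nrow(profs), 2)
  # boundary between the two regions lies on the wall column within 1 px
  boundary_cols <- which(apply(lab, 2, function(col) length(unique(col)) > 1))
  expect_true(all(abs(boundary_cols - 21) <= 1))
})

test_that("lattice membrane round-trip: one region per site, centroid on site", {
  lat <- generate_mosaic_lattice(3, 2)
  stack <- render_zstack(lat, surface_spec = list(mode = "flat", z0 = 8))
  surf <- reconstruct_olm_surface(stack, "zo1")
  boundary <- project_at_surface(stack, "zo1", surf, 2, "max")
  profs <- segment_profiles(boundary, lat[, c("x_um", "y_um")])
  expect_equal(nrow(profs), nrow(lat))
  d <- sqrt((profs$x_um[profs$profile_id] - lat$x_um)^2 +
              (profs$y_um[profs$profile_id] - lat$y_um)^2)
  expect_lt(max(d), 3 * boundary$pixel_size_um)
})

test_that("regions tile the field disjointly and conserve counts", {
  pr <- blank_projection()
  mask <- matrix(FALSE, 40, 40); mask[1:8, 1:8] <- TRUE
  expect_warning(
    profs <- segment_profiles(pr, rbind(c(2, 2), c(15, 15), c(10, 18)),
                              exclusion_mask = mask),
    "dropped")
  expect_equal(attr(profs, "n_dropped_seeds"), 1L)
  lab <- attr(profs, "label_image")
  expect_true(all(lab > 0))                       # full tiling
  expect_equal(sum(profs$label == "EXCLUDED", na.rm = TRUE), 1)
  expect_equal(sum(is.na(profs$label)), 2)        # usable seeds
  # conservation after classification
  profs$mean_intensity <- c(0.1, 0.9, NA)[seq_len(nrow(profs))]
  profs <- classify_kmeans(profs)
  expect_equal(sum(profs$label %in% c("POSITIVE", "NEGATIVE", "EXCLUDED")), nrow(profs))
})

test_that("zero usable seeds and duplicate seeds are rejected", {
  pr <- blank_projection()
  mask <- matrix(TRUE, 40, 40)
  expect_error(suppressWarnings(segment_profiles(pr, cbind(5, 5), exclusion_mask = mask)))
  expect_error(segment_profiles(pr, rbind(c(5.1, 5.1), c(5.2, 5.2))), "distinct")
})

test_that("intensity means match the brute-force pixel oracle", {
  pr <- blank_projection()
  profs <- segment_profiles(pr, rbind(c(5, 5), c(15, 15)))
  set.seed(9)
  rep_img <- matrix(stats::runif(40 * 40), 40, 40)
  reporter <- projection2d(rep_img, "red", 0.5, c(0, 0))
  m <- measure_intensity(profs, reporter)
  lab <- attr(profs, "label_image")
  for (i in 1:2) {
    expect_equal(m$mean_intensity[i], sum(rep_img[lab == i]) / sum(lab == i))
  }
  # uniform reporter: all means equal the constant
  uni <- measure_intensity(profs, projection2d(matrix(0.7, 40, 40), "red", 0.5, c(0, 0)))
  expect_equal(uni$mean_intensity, c(0.7, 0.7))
  # indicator of one profile
  ind <- projection2d((lab == 1) * 1, "red", 0.5, c(0, 0))
  mi <- measure_intensity(profs, ind)
  expect_equal(mi$mean_intensity, c(1, 0))
})

test_that("classification matches the exhaustive 1D two-cluster oracle", {
  make_profiles <- function(x) {
    tibble::tibble(profile_id = seq_along(x), x_um = 0, y_um = 0, area_um2 = 1,
                   mean_intensity = x, label = NA_character_)
  }
  set.seed(31)
  for (rep in 1:5) {
    x <- c(stats::runif(12, 0, 0.4), stats::runif(8, 0.5, 1))[sample(20)]
    got <- classify_kmeans(make_profiles(x))
    expect_identical(got$label == "POSITIVE", brute_two_cluster(x))
    # k-means route agrees on well-separated data
    km <- classify_kmeans(make_profiles(x), method = "kmeans")
    expect_identical(km$label, got$label)
  }
  # order invariance
  x <- c(0.1, 0.9, 0.15, 0.85, 0.2, 0.8)
  a <- classify_kmeans(make_profiles(x))$label
  b <- classify_kmeans(make_profiles(rev(x)))$label
  expect_identical(a, rev(b))
  # bimodal toy: 10 low + 10 high
  x2 <- c(rep(0.1, 10), rep(0.9, 10))
  lab2 <- classify_kmeans(make_profiles(x2))$label
  expect_equal(sum(lab2 == "POSITIVE"), 10)
  expect_identical(lab2[x2 > 0.5], rep("POSITIVE", 10))
  expect_error(classify_kmeans(make_profiles(rep(0.5, 6))), "unclassifiable")
})

test_that("ratios are plain count arithmetic and need a positive", {
  profs <- tibble::tibble(profile_id = 1:781, x_um = 0, y_um = 0, area_um2 = 1,
                          mean_intensity = 0,
                          label = c(rep("POSITIVE", 130), rep("NEGATIVE", 650),
                                    "EXCLUDED"))
  r <- compute_ratio(profs)
  expect_equal(r$ratio_negative, 5)
  expect_equal(r$n_excluded, 1)
  profs$label[profs$label == "POSITIVE"] <- "NEGATIVE"
  expect_error(compute_ratio(profs), "POSITIVE")
})

test_that("the auto-seeder finds one seed per cell on a clean membrane image", {
  lat <- generate_mosaic_lattice(2, 2)
  stack <- render_zstack(lat, surface_spec = list(mode = "flat", z0 = 8))
  surf <- reconstruct_olm_surface(stack, "zo1")
  boundary <- project_at_surface(stack, "zo1", surf, 2, "max")
  seeds <- auto_seed_profiles(boundary, smooth_sigma_px = 2, min_distance_px = 6)
  # every lattice site should have a proposed seed nearby
  d <- vapply(seq_len(nrow(lat)), function(i)
    min(sqrt((seeds$x_um - lat$x_um[i])^2 + (seeds$y_um - lat$y_um[i])^2)), numeric(1))
  expect_lt(stats::median(d), attr(lat, "spacing") / 2)
})
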