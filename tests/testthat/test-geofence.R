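test_that("haversine handles identity, one-degree and antipodal separations", {
  expect_equal(haversine_km(12.5, -70, 12.5, -70), 0)
  # one degree of longitude at the equator; frozen from the spherical
  # law-of-cosines oracle at R = 6371 km
  expect_equal(haversine_km(0, 0, 0, 1), 111.1949, tolerance = 1e-6)
  # half circumference: pi * 6371
  expect_equal(haversine_km(0, 0, 0, 180), pi * 6371, tolerance = 1e-9)
  expect_error(haversine_km(91, 0, 0, 0), "out of bounds")
})

test_that("haversine is symmetric and agrees with the law-of-cosines oracle", {
  set.seed(7)
  n <- 500
  lat1 <- runif(n, -90, 90); lon1 <- runif(n, -180, 180)
  lat2 <- runif(n, -90, 90); lon2 <- runif(n, -180, 180)
  d12 <- haversine_km(lat1, lon1, lat2, lon2)
  d21 <- haversine_km(lat2, lon2, lat1, lon1)
  expect_equal(d12, d21)
  oracle <- slc_km(lat1, lon1, lat2, lon2)
  sep <- oracle > 0.001  # oracle is ill-conditioned below ~1 m
  expect_true(all(abs(d12[sep] - oracle[sep]) / oracle[sep] < 1e-6))
})

test_that("load_pois filters by class and skips invalid rows", {
  csv <- tempfile(fileext = ".csv")
  df <- data.frame(
    id = paste0("p", 1:10),
    type = c(rep("large_airport", 4), rep("small_airport", 6)),
    name = paste("poi", 1:10),
    latitude_deg = as.character(seq(10, 19)),
    longitude_deg = as.character(seq(30, 39))
  )
  write.csv(df, csv, row.names = FALSE)
  expect_equal(nrow(load_pois(csv, "airport", "large_airport")), 4)
  expect_equal(nrow(load_pois(csv, "airport")), 10)

  df$latitude_deg[2] <- ""
  write.csv(df, csv, row.names = FALSE)
  expect_message(pois <- load_pois(csv, "airport"), "skipping 1")
  expect_equal(nrow(pois), 9)

  bad <- tempfile(fileext = ".csv")
  write.csv(data.frame(id = "x", name = "y"), bad, row.names = FALSE)
  expect_error(load_pois(bad, "airport"), "missing columns")
})

test_that("classification respects both fences, including the boundary", {
  hospitals <- tibble::tibble(poi_id = "h1", kind = "hospital", name = "h",
                              lat = 45, lon = 7, poi_class = "hospital")
  # airport 2 km east of the hospital: a point 0.1 km north of the
  # hospital is inside both fences simultaneously
  airport_near <- tibble::tibble(poi_id = "a1", kind = "airport", name = "a",
                                 lat = 45, lon = 7.0254,
                                 poi_class = "large_airport")
  p <- geosphere::destPoint(c(7, 45), 0, 100, r = 6371000)
  tw <- tibble::tibble(tweet_id = "x", lat = p[2], lon = p[1])
  mem <- classify_tweets(tw, airport_near, hospitals)
  expect_true(mem$in_hospital)
  expect_true(mem$in_airport)
  expect_equal(mem$collection, "both")

  # airport ~5 km east, point 0.25 km west of the hospital: outside both
  airport_far <- tibble::tibble(poi_id = "a2", kind = "airport", name = "a",
                                lat = 45, lon = 7.0636,
                                poi_class = "large_airport")
  p <- geosphere::destPoint(c(7, 45), 270, 250, r = 6371000)
  mem <- classify_tweets(tibble::tibble(tweet_id = "y", lat = p[2], lon = p[1]),
                         airport_far, hospitals)
  expect_false(mem$in_hospital)
  expect_false(mem$in_airport)
  expect_gt(mem$nearest_airport_km, 5)
  expect_equal(mem$collection, "geolocated")

  # exactly on the 3 km airport boundary: inclusive
  p <- geosphere::destPoint(c(7.0254, 45), 90, 3000, r = 6371000)
  mem <- classify_tweets(tibble::tibble(tweet_id = "z", lat = p[2], lon = p[1]),
                         airport_near, hospitals)
  expect_equal(mem$nearest_airport_km, 3, tolerance = 1e-9)
  expect_true(mem$in_airport)
})

test_that("membership flags satisfy the radius biconditional", {
  pois <- generate_pois(4, 6, seed = 3)
  sim <- generate_corpus(sim_config(seed = 3, n_tweets = 300), pois)
  mem <- classify_tweets(sim$tweets, pois$airports, pois$hospitals)
  expect_equal(mem$in_airport, mem$nearest_airport_km <= 3)
  expect_equal(mem$in_hospital, mem$nearest_hospital_km <= 0.2)
})

test_that("enlarging a radius never shrinks a membership set", {
  pois <- generate_pois(4, 6, seed = 5)
  sim <- generate_corpus(sim_config(seed = 5, n_tweets = 300), pois)
  radii <- c(0.5, 1, 3, 10, 50)
  prev <- NULL
  for (r in radii) {
    mem <- classify_tweets(sim$tweets, pois$airports, pois$hospitals,
                           airport_radius_km = r)
    ids <- mem$tweet_id[mem$in_airport]
    if (!is.null(prev)) expect_true(all(prev %in% ids))
    prev <- ids
  }
})

test_that("grid nearest-neighbour search matches brute force exactly", {
  pois <- generate_pois(10, 15, seed = 9)
  all_pois <- rbind(pois$airports, pois$hospitals)
  set.seed(9)
  n <- 200
  lat <- runif(n, -60, 60); lon <- runif(n, -180, 180)
  # include points very close to POIs so both regimes are exercised
  lat[1:20] <- all_pois$lat[1:20 %% nrow(all_pois) + 1] + runif(20, -0.01, 0.01)
  lon[1:20] <- all_pois$lon[1:20 %% nrow(all_pois) + 1] + runif(20, -0.01, 0.01)
  brute <- nearest_poi_km(lat, lon, all_pois, method = "brute")
  grid <- nearest_poi_km(lat, lon, all_pois, method = "grid")
  expect_equal(grid, brute, tolerance = 1e-9)
})

test_that("empty POI sets give infinite distances and false membership", {
  empty <- tibble::tibble(poi_id = character(0), kind = character(0),
                          name = character(0), lat = numeric(0),
                          lon = numeric(0), poi_class = character(0))
  mem <- classify_tweets(tibble::tibble(tweet_id = "a", lat = 0, lon = 0),
                         empty, empty)
  expect_equal(mem$nearest_airport_km, Inf)
  expect_false(mem$in_airport)
  expect_equal(mem$collection, "geolocated")
})
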