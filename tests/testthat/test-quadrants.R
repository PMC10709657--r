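test_that("quadrant bounds follow the zero crossings", {
  a <- ranked_list(data.frame(id = sprintf("g%02d", 1:10),
                              value = c(-4, -3, -2, -1, 1, 2, 3, 4, 5, 6)))
  b <- ranked_list(data.frame(id = sprintf("g%02d", 1:10),
                              value = c(-6, -5, -4, -3, -2, -1, 1, 2, 3, 4)))
  expect_equal(unname(quadrant_bounds(a, b, "dd")), c(4, 6))
  expect_equal(unname(quadrant_bounds(a, b, "uu")), c(6, 4))
  expect_equal(unname(quadrant_bounds(a, b, "du")), c(4, 4))
  expect_equal(unname(quadrant_bounds(a, b, "ud")), c(6, 6))

  # all-positive list a: dd and du collapse to zero extent
  ap <- ranked_list(data.frame(id = letters[1:4], value = 1:4))
  expect_equal(quadrant_bounds(ap, b, "dd")[["max_i"]], 0)
  expect_equal(quadrant_bounds(ap, b, "du")[["max_i"]], 0)
})

test_that("the four quadrants tile the global map without overlap", {
  sc <- make_scenario("four_block", n = 40, seed = 1)
  sa <- sc$a$split_index; sb <- sc$b$split_index; n <- sc$a$n
  # global-frame rectangles implied by the quadrant orientations
  areas <- c(dd = sa * sb, uu = (n - sa) * (n - sb),
             du = sa * (n - sb), ud = (n - sa) * sb)
  for (q in names(areas)) {
    bounds <- quadrant_bounds(sc$a, sc$b, q)
    expect_equal(prod(bounds), unname(areas[q]))
  }
  expect_equal(sum(areas), n * n)
})

test_that("enrichment sets are the oriented prefix intersections", {
  # hand-built 6-feature toy
  a <- ranked_list(data.frame(id = c("u", "v", "w", "x", "y", "z"),
                              value = c(-3, -2, -1, 1, 2, 3)))
  b <- ranked_list(data.frame(id = c("w", "u", "z", "x", "v", "y"),
                              value = c(-3, -2, -1, 1, 2, 3)))
  # dd at (2,2): {u,v} n {w,u} = {u}
  expect_equal(enrichment_set(a, b, "dd", 2, 2), "u")
  # uu at (3,3): {z,y,x} n {y,v,x} = {y,x}
  expect_setequal(enrichment_set(a, b, "uu", 3, 3), c("x", "y"))
  # du at (2,2): {u,v} n {y,v} = {v}
  expect_equal(enrichment_set(a, b, "du", 2, 2), "v")
  expect_error(enrichment_set(a, b, "dd", 4, 1), "outside quadrant")
})

test_that("identical lists: dd and uu capture the whole list between them", {
  sc <- make_scenario("identical", n = 1000, seed = 1)
  fit <- rrho(sc$a, sc$b, algorithm = "grid", step = 10, map = FALSE)
  dd <- fit$quadrants$dd; uu <- fit$quadrants$uu
  expect_true(dd$found && uu$found)
  expect_equal(sort(union(dd$enriched, uu$enriched)), sort(sc$a$labels))
  expect_equal(length(dd$enriched), dd$overlap)
  expect_equal(length(uu$enriched), uu$overlap)
})

test_that("reversed lists: signal only in du/ud, negative; du yields the full block", {
  sc <- make_scenario("reversed", n = 500, seed = 2)
  fit <- rrho(sc$a, sc$b, algorithm = "grid", step = 5, map = FALSE)
  td <- tidy(fit)
  expect_false(any(td$found[td$quadrant %in% c("dd", "uu")]))
  expect_true(all(td$found[td$quadrant %in% c("du", "ud")]))
  expect_true(all(td$signed_nlp[td$quadrant %in% c("du", "ud")] < 0))
  expect_equal(sort(fit$quadrants$du$enriched),
               sort(oriented_labels(sc$a, "down")[1:250]))
})

test_that("four-block lists produce four significant diagonal quadrants", {
  sc <- make_scenario("four_block", n = 1000, seed = 3)
  fit <- rrho(sc$a, sc$b, algorithm = "grid", step = 10, map = FALSE)
  td <- tidy(fit)
  expect_true(all(td$found))
  expect_true(all(-td$log_p > -log(0.05)))
  expect_equal(td$sign, c(1, 1, -1, -1))
  # split shifted to two fifths of the lists
  expect_equal(sc$a$split_index, 400)
})

test_that("empty quadrants are reported, not errors", {
  ap <- ranked_list(data.frame(id = sprintf("g%02d", 1:20), value = 1:20))
  bp <- ranked_list(data.frame(id = sprintf("g%02d", 1:20),
                               value = c(-(1:10), 1:10)))
  fit <- rrho(ap, bp, algorithm = "grid", step = 2, map = FALSE)
  td <- tidy(fit)
  expect_false(td$found[td$quadrant == "dd"])
  expect_equal(td$max_i[td$quadrant == "dd"], 0)
  expect_equal(td$n_enriched[td$quadrant == "dd"], 0)
})

test_that("rrho is reproducible under a fixed seed, including adjustment", {
  sc <- make_scenario("random", n = 300, seed = 4)
  f1 <- rrho(sc$a, sc$b, algorithm = "ea", adjust = "permutation",
             permutations = 20, map = FALSE, seed = 7)
  f2 <- rrho(sc$a, sc$b, algorithm = "ea", adjust = "permutation",
             permutations = 20, map = FALSE, seed = 7)
  expect_identical(tidy(f1), tidy(f2))
  expect_identical(f1$null, f2$null)
})

test_that("tidy/glance expose the broom-style views", {
  sc <- make_scenario("identical", n = 100, seed = 5)
  fit <- rrho(sc$a, sc$b, algorithm = "grid", step = 5, map = FALSE)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 4)
  g <- glance(fit)
  expect_equal(nrow(g), 1)
  expect_true(g$best_quadrant %in% c("dd", "uu"))
  expect_equal(g$n, 100)
})

test_that("results export echoes config and per-quadrant tables", {
  sc <- make_scenario("four_block", n = 200, seed = 6)
  fit <- rrho(sc$a, sc$b, algorithm = "grid", step = 5, map = TRUE,
              map_resolution = 20, seed = 3)
  dir <- withr::local_tempdir()
  write_rrho(fit, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "quadrant_dd.tsv", "quadrant_uu.tsv", "quadrant_du.tsv",
    "quadrant_ud.tsv", "overlap_map.tsv", "summary.json")))))
  js <- jsonlite::read_json(file.path(dir, "summary.json"))
  expect_equal(js$config$seed, 3)
  tab <- readr::read_tsv(file.path(dir, "quadrant_dd.tsv"),
                         show_col_types = FALSE)
  expect_equal(nrow(tab), fit$quadrants$dd$overlap)
  expect_named(tab, c("label", "rank_a", "rank_b", "value_a", "value_b"))
})
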