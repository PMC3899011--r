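test_that("fold-change boundary is inclusive and direction-specific", {
  expr <- tibble::tibble(
    probe_id = c("at_boundary", "repressed_probe", "just_below"),
    c1 = c(100, 100, 100), c2 = c(100, 100, 100),
    iso1 = c(200, 50, 199.9)
  )
  ind <- call_activation(expr, controls = c("c1", "c2"), "induced")
  rep_ <- call_activation(expr, controls = c("c1", "c2"), "repressed")
  expect_true(ind$calls["at_boundary", "iso1"])     # exactly 2-fold counts
  expect_false(ind$calls["just_below", "iso1"])
  expect_true(rep_$calls["repressed_probe", "iso1"]) # exactly 0.5-fold counts
  expect_false(ind$calls["repressed_probe", "iso1"])

  # induced and repressed calls are disjoint whenever threshold > 1
  set.seed(41)
  expr2 <- tibble::tibble(
    probe_id = sprintf("p%02d", 1:30),
    c1 = runif(30, 50, 150), c2 = runif(30, 50, 150),
    i1 = runif(30, 10, 400), i2 = runif(30, 10, 400)
  )
  for (thr in c(1.5, 2, 3)) {
    a <- call_activation(expr2, c("c1", "c2"), "induced", threshold = thr)
    b <- call_activation(expr2, c("c1", "c2"), "repressed", threshold = thr)
    expect_false(any(a$calls & b$calls))
  }
})

test_that("activation calls match an elementwise fold-change recomputation", {
  set.seed(7)
  n_probes <- 20
  ctrl <- matrix(runif(n_probes * 3, 20, 500), n_probes)
  trans <- matrix(runif(n_probes * 4, 5, 2000), n_probes)
  expr <- tibble::as_tibble(as.data.frame(cbind(ctrl, trans)))
  names(expr) <- c(paste0("ctrl", 1:3), paste0("iso", 1:4))
  expr <- tibble::add_column(expr, probe_id = sprintf("p%02d", 1:n_probes),
                             .before = 1)
  for (dir in c("induced", "repressed")) {
    act <- call_activation(expr, paste0("ctrl", 1:3), dir)
    for (g in seq_len(n_probes)) {
      m <- mean(ctrl[g, ])
      for (j in seq_len(4)) {
        fc <- trans[g, j] / m
        want <- if (dir == "induced") fc >= 2 else fc <= 0.5
        expect_identical(unname(act$calls[g, j]), want)
      }
    }
  }
})

test_that("per-isolate counts and full intersection match naive tallies", {
  calls <- matrix(FALSE, 12, 3)
  calls[1:10, ] <- TRUE
  act <- activation_matrix(calls)
  expect_equal(per_isolate_counts(act)$n_active, c(10, 10, 10))
  expect_equal(full_intersection_count(act), 10L)

  empty <- activation_matrix(matrix(FALSE, 5, 4))
  expect_equal(per_isolate_counts(empty)$n_active, rep(0L, 4))
  expect_equal(full_intersection_count(empty), 0L)

  # one never-active probe, everything else always active
  calls2 <- matrix(TRUE, 8, 5)
  calls2[3, ] <- FALSE
  expect_equal(full_intersection_count(activation_matrix(calls2)), 7L)

  set.seed(11)
  act3 <- random_activation(50, 5, 0.4)
  naive <- vapply(seq_len(5), function(j) {
    n <- 0L
    for (g in seq_len(50)) if (act3$calls[g, j]) n <- n + 1L
    n
  }, integer(1))
  expect_equal(per_isolate_counts(act3)$n_active, naive)
  sets <- apply(act3$calls, 2, which, simplify = FALSE)
  expect_equal(full_intersection_count(act3), length(Reduce(intersect, sets)))
})

test_that("mean overlap curve equals the subset-enumeration mean", {
  # identical active sets: every k-way intersection is the common set
  calls <- matrix(FALSE, 9, 4)
  calls[1:7, ] <- TRUE
  expect_equal(mean_overlap_curve(activation_matrix(calls))$y, rep(7, 4))

  # pairwise-disjoint sets of sizes 2, 4, 6: y = (mean sizes, 0, 0)
  calls2 <- matrix(FALSE, 12, 3)
  calls2[1:2, 1] <- TRUE; calls2[3:6, 2] <- TRUE; calls2[7:12, 3] <- TRUE
  expect_equal(mean_overlap_curve(activation_matrix(calls2))$y, c(4, 0, 0))

  set.seed(23)
  act <- random_activation(100, 6, 0.45)
  expect_equal(mean_overlap_curve(act)$y, enum_overlap_curve(act))
})

test_that("overlap curves are nonincreasing with matching endpoints", {
  set.seed(31)
  for (rep in 1:8) {
    n <- sample(2:8, 1)
    act <- random_activation(sample(20:80, 1), n, runif(1, 0.2, 0.8))
    curve <- mean_overlap_curve(act)
    expect_true(all(diff(curve$y) <= 1e-12))
    expect_equal(curve$y, enum_overlap_curve(act))
    expect_equal(curve$y[1], mean(per_isolate_counts(act)$n_active))
    expect_equal(curve$y[n], as.numeric(full_intersection_count(act)))
  }
})

test_that("probes with unusable control means are dropped, with a message", {
  expr <- tibble::tibble(
    probe_id = c("ok", "zero_ctrl", "neg_ctrl"),
    c1 = c(100, 0, -5), c2 = c(100, 0, 5),
    iso1 = c(300, 300, 300)
  )
  expect_message(
    act <- call_activation(expr, c("c1", "c2")),
    "2 probe"
  )
  expect_equal(rownames(act$calls), "ok")
  expect_error(call_activation(expr, character(0)), "control")
  expect_error(call_activation(expr, c("c1", "c2", "iso1")), "transformed")
})

test_that("activation and curve files round-trip through disk", {
  set.seed(5)
  act <- random_activation(30, 4, 0.5, direction = "repressed")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_activation_tsv(act, f)
  back <- read_activation_tsv(f, direction = "repressed")
  expect_identical(back$calls, act$calls)
  expect_identical(back$direction, "repressed")

  curve <- mean_overlap_curve(act)
  g <- withr::local_tempfile(fileext = ".csv")
  write_overlap_curve(curve, g)
  back2 <- read_overlap_curve(g, direction = "repressed")
  expect_equal(back2$y, curve$y)
})
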