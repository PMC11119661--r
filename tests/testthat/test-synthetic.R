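test_that("sampled parameter sets carry verified stability classes", {
  set.seed(41)
  for (i in 1:5) {
    pb <- sample_parameters("bistable")
    fp <- find_fixed_points(pb)
    expect_gte(sum(fp$stable), 2)
    st <- fp$x_star[fp$stable]
    expect_lte(max(st), 5)
    expect_gte(min(diff(sort(st))), 0.2)

    pm <- sample_parameters("monostable")
    expect_equal(sum(find_fixed_points(pm)$stable), 1)

    pf <- sample_parameters("flat")
    expect_equal(unname(pf[c("a", "b", "c")]), c(0, 0, 0))
    fpf <- find_fixed_points(pf)
    expect_true(all(fpf$boundary[fpf$stable]))
  }
})

test_that("noise-free generation reproduces the exact solution", {
  spec <- synthetic_spec(n_genes = 1, noise_sd = 0, n_pc = 30, seed = 2)
  p <- model_parameters(c = 0.4, d = 1.2)
  set.seed(7)
  g <- generate_gene(p, spec, x0 = 0.8)
  tg <- g$trajectory$t
  expect_equal(g$trajectory$x, linear_solution(0.8, 0.4, 1.2, tg),
               tolerance = 1e-6)
})

test_that("generation is seed-deterministic with the stated noise level", {
  spec <- synthetic_spec(n_genes = 4, seed = 13)
  d1 <- generate_dataset(spec)
  d2 <- generate_dataset(spec)
  expect_identical(d1, d2)

  # residual SD against the noise-free curve matches noise_sd
  spec2 <- synthetic_spec(n_genes = 30, noise_sd = 0.02, seed = 14)
  dat <- generate_dataset(spec2)
  sds <- vapply(seq_len(nrow(dat$truth)), function(i) {
    row <- dat$truth[i, ]
    tr <- dplyr::filter(dat$trajectories, gene_id == row$gene_id)
    xm <- integrate_trajectory(as_parameters(row), row$x0, tr$t)$x
    stats::sd(tr$x - xm)
  }, 0)
  expect_gte(mean(sds >= 0.013 & sds <= 0.027), 0.9)
})

test_that("datasets honor the class mix and the trajectory invariants", {
  spec <- synthetic_spec(n_genes = 10,
                         class_mix = c(monostable = 0.5, bistable = 0.3,
                                       flat = 0.2),
                         n_pc = 20, seed = 15)
  dat <- generate_dataset(spec)
  expect_equal(unname(table(dat$truth$class)[c("monostable", "bistable",
                                               "flat")]),
               c(5L, 3L, 2L), ignore_attr = TRUE)
  per_gene <- dat$trajectories |>
    dplyr::group_by(gene_id) |>
    dplyr::summarise(n = dplyr::n(), inc = all(diff(t) > 0),
                     clamped = all(x >= EXPR_CLAMP), .groups = "drop")
  expect_true(all(per_gene$n == 20))
  expect_true(all(per_gene$inc))
  expect_true(all(per_gene$clamped))

  # cross-module contract: truth labels agree with the stability analysis
  for (i in seq_len(nrow(dat$truth))) {
    row <- dat$truth[i, ]
    n_st <- sum(find_fixed_points(as_parameters(row))$stable)
    expected <- switch(row$class, flat = 1L, monostable = 1L, bistable = 2L)
    if (row$class == "bistable") expect_gte(n_st, 2) else
      expect_equal(n_st, expected)
  }

  # different seeds, same schema, different values
  d2 <- generate_dataset(synthetic_spec(n_genes = 10,
                                        class_mix = c(monostable = 0.5,
                                                      bistable = 0.3,
                                                      flat = 0.2),
                                        n_pc = 20, seed = 16))
  expect_identical(names(d2$trajectories), names(dat$trajectories))
  expect_false(identical(d2$trajectories$x, dat$trajectories$x))
})

test_that("per-cell data layer supports resmoothing at chosen resolutions", {
  cd <- generate_cell_data(synthetic_spec(n_genes = 2, seed = 23),
                           n_cells = 80)
  expect_setequal(names(cd$cells), c("gene_id", "t", "x"))
  expect_equal(dplyr::n_distinct(cd$cells$gene_id), 2)
  tr <- resmooth_at_npc(cd$cells, npc = 15)
  expect_equal(nrow(tr), 30)
  expect_true(all(tr$x >= EXPR_CLAMP))
  counts <- tr |> dplyr::count(gene_id)
  expect_true(all(counts$n == 15))
})
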