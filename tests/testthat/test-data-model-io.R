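test_that("connectivity matrices survive a write/read round trip and are validated", {
  dir <- withr::local_tempdir()
  fc <- random_symmetric_fc(6, seed = 2)
  path <- file.path(dir, "s1.tsv")
  write_connectivity_matrix(fc, path)
  back <- read_connectivity_matrix(path, 6)
  expect_equal(unclass(back), unclass(fc), tolerance = 1e-12)

  # identity read-back of a literal 3x3 table
  writeLines(c("0\t0.1\t0.2", "0.1\t0\t0.3", "0.2\t0.3\t0"), file.path(dir, "lit.tsv"))
  lit <- read_connectivity_matrix(file.path(dir, "lit.tsv"), 3)
  expect_equal(vectorize_edges(lit), c(0.1, 0.2, 0.3))

  writeLines(c("0\t0.1\t0.3", "0.1\t0\t0.3", "0.4\t0.3\t0"), file.path(dir, "asym.tsv"))
  expect_error(read_connectivity_matrix(file.path(dir, "asym.tsv"), 3), "not symmetric")

  writeLines(c("0\t0.1\t0.2", "0.1\t0\t0.3"), file.path(dir, "dim.tsv"))
  expect_error(read_connectivity_matrix(file.path(dir, "dim.tsv"), 3), "dimension mismatch")

  writeLines(c("0\tx\t0.2", "x\t0\t0.3", "0.2\t0.3\t0"), file.path(dir, "nonnum.tsv"))
  expect_error(read_connectivity_matrix(file.path(dir, "nonnum.tsv"), 3), "non-numeric")
})

test_that("behavior tables keep missing cells and reject malformed input", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "beh.tsv")
  writeLines(c("subject_id\tias\tage\tdepression",
               "S1\t101\t19\t7",
               "S2\t95\t21\t",
               "S3\t130\t18\t12"), path)
  beh <- read_behavior_table(path, "ias", c("age", "depression"))
  expect_equal(nrow(beh), 3)
  expect_true(is.na(beh$depression[2]))
  expect_false(anyNA(beh$ias))

  writeLines(c("subject_id\tias", "S1\t101", "S1\t95"), path)
  expect_error(read_behavior_table(path, "ias"), "duplicate subject id")

  writeLines(c("subject_id\tias", "S1\t101"), path)
  expect_error(read_behavior_table(path, "ias", "age"), "missing required column")
})

test_that("assemble_dataset stacks edge vectors in record order", {
  mats <- list(A = random_symmetric_fc(4, 1), B = random_symmetric_fc(4, 2))
  beh <- data.frame(subject_id = c("B", "A"), score = c(10, 20))
  ds <- assemble_dataset(mats, beh, "score")
  expect_equal(dim(ds$edge_matrix), c(2L, 6L))     # 4*3/2 edges
  expect_equal(ds$edge_matrix[1, ], vectorize_edges(mats$B))
  expect_equal(ds$edge_matrix[2, ], vectorize_edges(mats$A))

  expect_error(assemble_dataset(mats["A"], beh, "score"), "no connectivity matrix.*B")
  expect_error(assemble_dataset(mats, beh[0, , drop = FALSE], "score"), "no subjects")
  mats$B <- random_symmetric_fc(5, 2)
  expect_error(assemble_dataset(mats, beh, "score"), "differ in node count")
})

test_that("edge masks round-trip exactly", {
  dir <- withr::local_tempdir()
  N <- 12; E <- n_edges(N)
  withr::with_seed(5, {
    mask <- runif(E) < 0.2
    w <- rnorm(E)
  })
  path <- file.path(dir, "mask.tsv")
  write_edge_mask(mask, N, path, weights = w)
  back <- read_edge_mask(path, N)
  expect_identical(back$mask, mask)
  expect_equal(back$weights[mask], w[mask], tolerance = 1e-12)
  expect_error(read_edge_mask(path, 13), "N=12")
})

test_that("atlas validation enforces complete 0..N-1 coverage", {
  atlas <- synthetic_atlas(20)
  expect_s3_class(atlas, "cpm_atlas")
  expect_equal(atlas$node_id, 0:19)
  bad <- as.data.frame(atlas)
  bad$node_id[3] <- 99
  expect_error(as_cpm_atlas(bad), "0..N-1")
  bad2 <- as.data.frame(atlas)
  bad2$macroscale_region[1] <- ""
  expect_error(as_cpm_atlas(bad2), "macroscale_region")
})

test_that("run_pipeline writes deterministic artifacts and honours config", {
  ds <- generate_dataset(synthetic_spec(n_subjects = 25, n_nodes = 12, seed = 42,
                                        signal_edges = data.frame(i = 0, j = 1,
                                                                  beta = -0.8)))
  atlas <- synthetic_atlas(12)
  cfg <- cpm_config(n_permutations = 19, rng_seed = 42)

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  run_pipeline(ds$dataset, atlas, cfg, d1)
  run_pipeline(ds$dataset, atlas, cfg, d2)
  for (f in c("report.json", "predictions.tsv", "contributing_negative.tsv",
              "null_distribution.tsv", "node_strength_negative.tsv",
              "macroscale_counts_negative.tsv")) {
    expect_true(file.exists(file.path(d1, f)), info = f)
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = paste("bytes of", f))
  }
  rep <- jsonlite::read_json(file.path(d1, "report.json"))
  expect_equal(rep$n_edges, n_edges(12))
  expect_false(is.null(rep$performance$negative$permutation_p))

  # permutations disabled: p absent from the report
  rep0 <- run_pipeline(ds$dataset, atlas, cpm_config(n_permutations = 0, rng_seed = 1))
  expect_null(rep0$performance$negative$permutation_p)

  # guard: too few subjects for selection
  tiny <- generate_dataset(synthetic_spec(n_subjects = 4, n_nodes = 6, seed = 1,
                                          signal_edges = data.frame(i = 0, j = 1,
                                                                    beta = -0.5)))
  expect_error(run_pipeline(tiny$dataset, synthetic_atlas(6),
                            cpm_config(n_permutations = 0)),
               "insufficient sample")
})
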