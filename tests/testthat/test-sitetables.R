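test_that("site table round-trips through TSV, preserving values and missingness", {
  design <- design_invivo()
  tab <- rand_invivo_table(10, design, miss = 0.3, seed = 42)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_site_table(tab, path)
  back <- suppressMessages(read_site_table(path, design))
  expect_equal(back$values, tab$values)
  expect_equal(back$meta$protein_id, tab$meta$protein_id)
  expect_equal(back$meta$position, tab$meta$position)
  expect_identical(is.na(back$values), is.na(tab$values))
  # missing cells serialized as NaN on disk
  expect_true(any(grepl("NaN", readLines(path))))
  # two writes are byte-identical (deterministic header/column order)
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_site_table(tab, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("malformed numeric cells reject the row with a warning", {
  design <- design_invivo(n_replicates = 2)
  tab <- rand_invivo_table(3, design, miss = 0, seed = 1)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_site_table(tab, path)
  lines <- readLines(path)
  lines[2] <- sub("^(\\S+\t\\S+\t\\S+\t\\S+\t)\\S+", "\\11,5", lines[2])
  writeLines(lines, path)
  expect_warning(back <- suppressMessages(read_site_table(path, design)),
                 "malformed")
  expect_equal(n_sites(back), 2)
})

test_that("duplicate site keys and absent design samples are hard errors", {
  design <- design_invivo(n_replicates = 2)
  tab <- rand_invivo_table(3, design, miss = 0, seed = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_site_table(tab, path)
  lines <- readLines(path)
  writeLines(c(lines, lines[2]), path)
  expect_error(suppressMessages(read_site_table(path, design)), "duplicated")

  writeLines(lines, path)
  bigger <- design_invivo(n_replicates = 3)
  err <- tryCatch(suppressMessages(read_site_table(path, bigger)),
                  error = conditionMessage)
  expect_match(err, "vehicle_5min_r3")  # names the missing sample

  # duplicate (protein, position) also rejected at construction
  meta <- data.frame(protein_id = c("A", "A"), position = c(10L, 10L),
                     residue = "S", localization_probability = 0.9)
  vals <- matrix(0, 2, nrow(design), dimnames = list(NULL, design$sample_id))
  expect_error(site_table(meta, vals, design), "A\\|10")
})

test_that("localization filter is strictly greater-than", {
  design <- design_invivo(n_replicates = 2)
  tab <- rand_invivo_table(3, design, miss = 0, seed = 3,
                           loc_prob = c(0.74, 0.75, 0.76))
  kept <- suppressMessages(filter_localization(tab, 0.75))
  expect_equal(n_sites(kept), 1)
  expect_equal(kept$meta$localization_probability, 0.76)
  # threshold 0 keeps everything with positive probability
  expect_equal(n_sites(suppressMessages(filter_localization(tab, 0))), 3)
})

test_that("localization filter kept fraction matches the Beta tail", {
  n <- 5000
  set.seed(11)
  tab <- rand_invivo_table(n, design_invivo(n_replicates = 2), miss = 0,
                           seed = 11, loc_prob = rbeta(n, 9, 1))
  kept <- n_sites(suppressMessages(filter_localization(tab, 0.75)))
  p <- 1 - pbeta(0.75, 9, 1)
  bounds <- qbinom(c(0.005, 0.995), n, p)
  expect_gte(kept, bounds[1])
  expect_lte(kept, bounds[2])
})

test_that("protein replicate filter matches a per-row counting oracle", {
  design <- design_invivo()
  set.seed(4)
  n <- 100
  vals <- matrix(rnorm(n * nrow(design)), n,
                 dimnames = list(NULL, design$sample_id))
  vals[matrix(runif(length(vals)) < 0.7, n)] <- NA
  pt <- protein_table(sprintf("P%03d", 1:n), vals, design)
  kept <- suppressMessages(filter_protein_min_replicates(pt, 2))
  cell <- interaction(design$arm, design$timepoint_min)
  oracle <- vapply(seq_len(n), function(i) {
    any(tapply(!is.na(vals[i, ]), cell, sum) >= 2)
  }, TRUE)
  expect_setequal(kept$meta$protein_id, sprintf("P%03d", which(oracle)))

  # observed in 2 of 5 vehicle-5min replicates only -> kept at min 2
  v <- matrix(NA_real_, 1, nrow(design), dimnames = list(NULL, design$sample_id))
  v[1, c("vehicle_5min_r1", "vehicle_5min_r2")] <- c(0.5, 0.7)
  one <- protein_table("X", v, design)
  expect_equal(nrow(suppressMessages(
    filter_protein_min_replicates(one, 2))$values), 1)
  # all-missing protein dropped
  v[] <- NA
  none <- protein_table("X", v, design)
  expect_equal(nrow(suppressMessages(
    filter_protein_min_replicates(none, 2))$values), 0)
})

test_that("protein normalization subtracts per-sample protein ratios", {
  design <- design_invivo(n_replicates = 2)
  tab <- rand_invivo_table(4, design, miss = 0, seed = 5)
  tab$values[] <- 2.0
  pv <- matrix(0.5, 2, nrow(design), dimnames = list(NULL, design$sample_id))
  pt <- protein_table(tab$meta$protein_id[1:2], pv, design)
  out <- suppressMessages(normalize_to_protein(tab, pt))
  expect_equal(unname(out$values[1, 1]), 1.5)
  # sites without protein coverage kept unnormalized and flagged
  expect_equal(unname(out$values[3, 1]), 2.0)
  expect_equal(out$meta$protein_normalized, c(TRUE, TRUE, FALSE, FALSE))
  # zero protein values leave sites unchanged
  pv0 <- matrix(0, 4, nrow(design), dimnames = list(NULL, design$sample_id))
  pt0 <- protein_table(tab$meta$protein_id, pv0, design)
  expect_equal(suppressMessages(normalize_to_protein(tab, pt0))$values,
               tab$values)
})

test_that("protein normalization reduces variance of drifting null sites", {
  cfg <- sim_config(n_proteins = 150, n_targets = 0, protein_drift_sd = 0.4,
                    mnar_slope = 0, mcar_rate = 0, seed = 6)
  sim <- generate_invivo(cfg)
  norm <- suppressMessages(normalize_to_protein(sim$sites, sim$proteins))
  expect_lt(var(as.vector(norm$values)), var(as.vector(sim$sites$values)))
})

test_that("site replicate filter implements the either-timepoint rule", {
  design <- design_invivo()
  tab <- rand_invivo_table(2, design, miss = 0, seed = 7)
  tab$values[] <- NA
  # site 1: 3 vehicle-5min values, none at 15 min -> kept with min 3
  tab$values[1, c("vehicle_5min_r1", "vehicle_5min_r2", "vehicle_5min_r3")] <- 1
  # site 2: 2 and 2 -> dropped
  tab$values[2, c("vehicle_5min_r1", "vehicle_5min_r2",
                  "vehicle_15min_r1", "vehicle_15min_r2")] <- 1
  kept <- suppressMessages(filter_site_min_quantified(tab, min_replicates = 3))
  expect_equal(n_sites(kept), 1)
  expect_equal(kept$meta$protein_id, tab$meta$protein_id[1])

  # brute-force row scan on a random 500-row table
  big <- rand_invivo_table(500, design, miss = 0.6, seed = 8)
  kept <- suppressMessages(filter_site_min_quantified(big, min_replicates = 3))
  c5 <- paste0("vehicle_5min_r", 1:5)
  c15 <- paste0("vehicle_15min_r", 1:5)
  oracle <- rowSums(!is.na(big$values[, c5])) >= 3 |
    rowSums(!is.na(big$values[, c15])) >= 3
  expect_equal(n_sites(kept), sum(oracle))
  expect_equal(rownames(kept$values), rownames(big$values)[oracle])
})

test_that("filters are idempotent and never alter retained values", {
  design <- design_invivo()
  tab <- rand_invivo_table(200, design, miss = 0.4, seed = 9)
  suppressMessages({
    f1 <- filter_localization(tab, 0.5)
    f2 <- filter_localization(f1, 0.5)
    expect_identical(f1, f2)
    g1 <- filter_site_min_quantified(tab, min_replicates = 3)
    g2 <- filter_site_min_quantified(g1, min_replicates = 3)
    expect_identical(g1, g2)
  })
  keys <- intersect(rownames(tab$values), rownames(f1$values))
  expect_identical(tab$values[keys, ], f1$values[keys, ])
})

test_that("normalization commutes with sample-column permutation", {
  design <- design_invivo(n_replicates = 2)
  tab <- rand_invivo_table(10, design, miss = 0.1, seed = 10)
  pv <- matrix(rnorm(10 * nrow(design)), 10,
               dimnames = list(NULL, design$sample_id))
  pt <- protein_table(tab$meta$protein_id, pv, design)
  out1 <- suppressMessages(normalize_to_protein(tab, pt))

  perm <- sample(nrow(design))
  design_p <- design[perm, ]
  tab_p <- site_table(tab$meta, tab$values[, design_p$sample_id],
                      design_p)
  pt_p <- protein_table(pt$meta$protein_id, pv[, design_p$sample_id],
                        design_p)
  out2 <- suppressMessages(normalize_to_protein(tab_p, pt_p))
  expect_equal(out2$values, out1$values[, design_p$sample_id])
})
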