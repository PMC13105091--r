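test_that("interaction tables load, validate, and deduplicate", {
  txt <- paste("odorant_id,smiles,receptor_id,sequence,response",
               "o1,CCO,r1,MKTAY,1.0",
               "o1,CCO,r2,GGWLP,2.0",
               "o2,CCC,r1,MKTAY,3.0", sep = "\n")
  ds <- load_interaction_table(txt, mode = "regression")
  expect_s3_class(ds, "interaction_dataset")
  expect_equal(n_interactions(ds), 3)
  expect_equal(attr(ds, "n_deduplicated"), 0L)

  # duplicated pair averages in regression mode
  dup <- paste(txt, "o1,CCO,r1,MKTAY,3.0", sep = "\n")
  expect_warning(ds2 <- load_interaction_table(dup, mode = "regression"),
                 "duplicate")
  it <- ds2$interactions
  expect_equal(it$response[it$odorant_id == "o1" & it$receptor_id == "r1"], 2)
  expect_equal(attr(ds2, "n_deduplicated"), 1L)

  # schema mapping of arbitrary headers
  txt2 <- paste("mol,SMILES,rec,seq,spike_rate",
                "o1,CCO,r1,MKTAY,1.5", "o2,CCC,r1,MKTAY,0.5", sep = "\n")
  ds3 <- load_interaction_table(
    txt2, mode = "regression",
    schema = c(odorant_id = "mol", smiles = "SMILES", receptor_id = "rec",
               sequence = "seq", response = "spike_rate"))
  expect_equal(ds3$interactions$response, c(1.5, 0.5))
  expect_error(load_interaction_table(txt2, mode = "regression"),
               "missing required column")
})

test_that("classification loading enforces the label domain and majority rule", {
  txt <- paste("smiles,sequence,label",
               "CCO,MKTAY,1", "CCC,MKTAY,2", sep = "\n")
  expect_error(load_interaction_table(txt, mode = "classification"),
               "labels must be 0 or 1")
  tie <- paste("smiles,sequence,label",
               "CCO,MKTAY,1", "CCO,MKTAY,0", sep = "\n")
  expect_error(suppressWarnings(
    load_interaction_table(tie, mode = "classification")), "no majority")
  maj <- paste("smiles,sequence,label",
               "CCO,MKTAY,1", "CCO,MKTAY,1", "CCO,MKTAY,0",
               "CCC,MKTAY,0", sep = "\n")
  expect_warning(ds <- load_interaction_table(maj, mode = "classification"))
  expect_equal(ds$interactions$label[ds$interactions$odorant_id == "CCO"], 1L)
})

test_that("interaction table writing round-trips a validated dataset", {
  ds <- tiny_panel()
  ds$odorants$smiles[1] <- "CCC#N"  # '#' must survive the CSV round trip
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  write_interaction_table(ds, f)
  back <- load_interaction_table(f, mode = "regression")
  expect_equal(back$interactions$response, ds$interactions$response)
  expect_equal(back$odorants$smiles, ds$odorants$smiles)
  expect_equal(back$receptors$sequence, ds$receptors$sequence)
})

test_that("FASTA loading joins lines, uppercases, and validates", {
  recs <- load_receptor_fasta(">OR1 some description\nMKT\nLLV\n>OR2\nacdy\n")
  expect_equal(recs$receptor_id, c("OR1", "OR2"))
  expect_equal(recs$sequence, c("MKTLLV", "ACDY"))
  expect_error(load_receptor_fasta(">A\n>B\nMK\n"), "A")
  expect_error(load_receptor_fasta(">A\nMK\n>A\nPL\n"), "duplicate")
})

test_that("global z-scoring pools all responses and is idempotent", {
  ds <- tiny_panel()
  ds$interactions$response <- c(0, 10, 0, 10)
  z <- zscore_global(ds)
  expect_equal(sort(unique(z$dataset$interactions$response)), c(-1, 1))
  expect_equal(z$params$mu, 5)
  expect_equal(z$params$sigma, 5)  # population SD
  z2 <- zscore_global(z$dataset)
  expect_lt(max(abs(z2$dataset$interactions$response -
                      z$dataset$interactions$response)), 1e-10)
  expect_lt(abs(z2$params$mu), 1e-12)
  expect_equal(z2$params$sigma, 1, tolerance = 1e-12)
  ds$interactions$response <- rep(2, 4)
  expect_error(zscore_global(ds), "sigma = 0")
})

test_that("the neural representation lays out responses odorant x receptor", {
  ds <- tiny_panel()
  nr <- build_neural_representation(ds)
  expect_equal(unname(nr$values), matrix(c(1, 3, 2, 4), 2))
  expect_equal(nr$item_ids, c("o1", "o2"))
  # missing pair: error by default, zero under fill policy
  ds2 <- ds
  ds2$interactions <- ds2$interactions[-4, ]
  expect_error(build_neural_representation(ds2), "o2, r2")
  nr2 <- build_neural_representation(ds2, missing_policy = "fill_zero")
  expect_equal(unname(nr2$values[2, 2]), 0)
})

test_that("neural representation matches stored responses on random datasets", {
  for (s in 1:10) {
    set.seed(s)
    n_o <- sample(3:8, 1); n_r <- sample(2:6, 1)
    panel <- gen_panel(n_o, n_r, seed = s)
    nr <- build_neural_representation(panel$dataset)
    it <- panel$dataset$interactions
    for (k in sample(nrow(it), min(10, nrow(it)))) {
      i <- match(it$odorant_id[k], nr$item_ids)
      j <- match(it$receptor_id[k],
                 panel$dataset$receptors$receptor_id)
      expect_identical(nr$values[i, j], it$response[k])
    }
  }
})

test_that("representation matrices validate and round-trip through CSV", {
  expect_error(representation_matrix(matrix(1:4, 2), c("a", "b", "c")),
               "row count")
  expect_error(representation_matrix(matrix(c(1, NA, 3, 4), 2), c("a", "b")),
               "finite")
  rm_ <- representation_matrix(matrix(rnorm(12), 4), letters[1:4], "test")
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  write_representation(rm_, f)
  back <- read_representation(f, name = "test")
  expect_equal(unname(back$values), unname(rm_$values))
  expect_equal(back$item_ids, rm_$item_ids)
})
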