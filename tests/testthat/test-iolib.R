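test_that("read_measurements groups rows into age-ordered assemblages", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("locality,age_ma,area",
               "B,425,1.0", "B,425,1.2",
               "A,430,2.0", "A,430,2.2", "A,430,2.4"), f)
  ser <- read_measurements(f)
  expect_length(ser, 2L)
  expect_equal(vapply(ser, `[[`, character(1), "locality"), c("A", "B"))
  expect_equal(vapply(ser, `[[`, integer(1), "n"), c(3L, 2L))
  expect_equal(ser[[2]]$areas, c(1.0, 1.2))   # area taken verbatim
})

test_that("read_measurements computes areas from length/width when absent", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("locality,age_ma,length,width",
               "A,430,2,1", "A,430,3,2"), f)
  expect_equal(read_measurements(f)[[1]]$areas, c(2, 6))
  expect_equal(read_measurements(f, "ellipse")[[1]]$areas,
               (pi / 4) * c(2, 6))
})

test_that("read_measurements error contracts name the problem", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("site,age_ma,area", "A,430,1"), f)   # renamed locality
  expect_error(read_measurements(f), "locality")

  writeLines(c("locality,age_ma,area", "A,430,1", "A,430,oops"), f)
  expect_error(read_measurements(f), "row 2")
})

test_that("measurement round trip preserves values to full precision", {
  ser <- toy_series(seed = 3)
  f <- withr::local_tempfile(fileext = ".csv")
  write_measurements(ser, f)
  back <- read_measurements(f)
  expect_equal(vapply(back, `[[`, character(1), "locality"),
               vapply(ser, `[[`, character(1), "locality"))
  for (i in seq_along(ser)) expect_equal(back[[i]]$areas, ser[[i]]$areas)
})

test_that("NEXUS character matrix parsing and error contracts", {
  f <- withr::local_tempfile(fileext = ".nex")
  writeLines(c("#NEXUS", "BEGIN DATA;",
               "DIMENSIONS NTAX=3 NCHAR=5;",
               "FORMAT DATATYPE=STANDARD MISSING=? GAP=- SYMBOLS=\"01\";",
               "MATRIX", "TaxA 01?-1", "TaxB 11111", "TaxC 00000",
               ";", "END;"), f)
  m <- read_nexus_matrix(f)
  expect_equal(c(m$n_taxa, m$n_chars), c(3L, 5L))
  expect_equal(m$states[1], "01?-1")          # ? and - kept distinct
  miss <- matrix_missingness(m)
  expect_equal(miss$unknown, 1L)
  expect_equal(miss$inapplicable, 1L)

  writeLines(c("#NEXUS", "BEGIN DATA;",
               "DIMENSIONS NTAX=2 NCHAR=5;",
               "FORMAT DATATYPE=STANDARD MISSING=? GAP=-;",
               "MATRIX", "TaxA 011", "TaxB 11111", ";", "END;"), f)
  expect_error(read_nexus_matrix(f), "format error")

  writeLines(c("#NEXUS", "BEGIN DATA;",
               "DIMENSIONS NTAX=2 NCHAR=3;",
               "FORMAT DATATYPE=STANDARD MISSING=? GAP=-;",
               "MATRIX", "TaxA 011", "TaxA 111", ";", "END;"), f)
  expect_error(read_nexus_matrix(f), "format error")
})

test_that("tree reading applies the sampled-ancestor conventions", {
  smp <- sample_from_newick(c(
    "((b:1,a:0):1,c:2);",            # zero pendant -> SA
    "((b:1,a:0.5):1,c:2);",          # 0.5 Myr pendant -> not SA
    "((b:1,a:0.5[&SA]):1,c:2);",     # annotation overrides length
    "((b:1,a:0):1,c:2);"))
  expect_equal(smp$n_trees, 4L)
  sa_a <- vapply(smp$trees, function(t) unname(t$sampled_ancestor["a"]),
                 logical(1))
  expect_equal(sa_a, c(TRUE, FALSE, TRUE, TRUE))
})

test_that("tree reading errors: unparseable string, negative length", {
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines(c("((a:1,b:1):1,c:1);", "((a:1,b:1:1,c);"), f)
  expect_error(read_tree_sample(f), "index 2")
  writeLines("((a:-1,b:1):1,c:1);", f)
  expect_error(read_tree_sample(f), "negative branch length")
})

test_that("tree sample round trip keeps topology, lengths, flags, rates", {
  smp <- gen_tree_sample(5, letters[1:6], 0.6, seed = 11)
  for (i in seq_len(5))
    smp$trees[[i]]$edge_rate <- seq_len(nrow(smp$trees[[i]]$edge)) * 1.5
  f <- withr::local_tempfile(fileext = ".nwk")
  write_tree_sample(smp, f)
  back <- read_tree_sample(f)
  for (i in seq_len(5)) {
    t1 <- smp$trees[[i]]; t2 <- back$trees[[i]]
    expect_true(ape::all.equal.phylo(t1, t2, use.edge.length = TRUE))
    expect_equal(t1$sampled_ancestor[sort(t1$tip.label)],
                 t2$sampled_ancestor[sort(t2$tip.label)])
    expect_equal(t1$edge_rate, t2$edge_rate)
  }
})

test_that("occurrence reading dedupes and validates intervals", {
  st <- toy_stages(4L)
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("taxon,interval", "A,I1", "A,I2", "A,I2", "B,I3", "B,I4"), f)
  occ <- read_occurrences(f, st)
  expect_equal(sum(occ$presence), 4L)

  writeLines("taxon,interval", f)
  empty <- read_occurrences(f, st)
  expect_equal(sum(empty$presence), 0L)

  writeLines(c("taxon,interval", "A,Zork"), f)
  expect_error(read_occurrences(f, st), "Zork")
})

test_that("stage table and FBD posterior readers validate their input", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("name,start_ma,end_ma", "S2,430,425", "S1,435,430"), f)
  st <- read_stage_table(f)
  expect_equal(st$name, c("S1", "S2"))   # reordered oldest first
  writeLines(c("name,start_ma,end_ma", "S1,425,430"), f)
  expect_error(read_stage_table(f), "start_ma")

  writeLines(c("stage,lambda,mu,psi", "S1,0.2,0.1,0.3"), f)
  post <- read_fbd_posterior(f)
  expect_equal(post$psi, 0.3)
  writeLines(c("stage,lambda,mu", "S1,0.2,0.1"), f)
  expect_error(read_fbd_posterior(f), "psi")
})

test_that("run_config validates and round-trips through JSON", {
  cfg <- run_config(seed = 9, n_sims = 50, tail = "two_sided",
                    measurements = "m.csv")
  expect_s3_class(cfg, "run_config")
  expect_error(run_config(n_sims = 0), "n_sims")
  f <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(seed = 9, n_sims = 50, tail = "two_sided"),
                       f, auto_unbox = TRUE)
  cfg2 <- read_run_config(f)
  expect_equal(cfg2$n_sims, 50L)
  expect_equal(cfg2$tail, "two_sided")
})
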