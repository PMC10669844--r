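test_that("plant table parsing normalises activities and flags evidence", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_plant_fixture(path)
  plants <- read_plant_table(path)
  expect_equal(nrow(plants), 3)
  expect_equal(plants$activities[[1]], c("AOX", "AAG"))
  expect_equal(plants$activities[[2]], character(0))
  expect_false(plants$has_evidence[2])
  expect_true(plants$has_evidence[3])
  expect_equal(plants$activities[[3]], "AINF")
  expect_equal(plants$compound_ids[[2]], c("C2", "C3"))
})

test_that("plant table schema violations are located", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("plant_id\tfamily\tgenus\tspecies\tactivities",
               "P1\tA\tB\tC\t"), path)
  expect_error(read_plant_table(path), "compounds")

  write_plant_fixture(path, rows = c(
    "P1\tA\tB\tc1\t\t", "P1\tA\tB\tc2\t\t"))
  expect_error(read_plant_table(path), "duplicate plant_id: P1")

  write_plant_fixture(path, rows = "P1\tA\t \tc1\t\t")
  expect_error(read_plant_table(path), "empty genus at row 1")
})

test_that("unknown activity tokens are preserved, not dropped", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_plant_fixture(path, rows = "P1\tA\tB\tc\tantioxidant;antitussive\tC1")
  plants <- read_plant_table(path)
  expect_equal(plants$activities[[1]], "AOX")
  expect_true("activity_token=antitussive" %in% plants$other_annotations[[1]])
})

test_that("synonymous species rows merge on (genus, species), case-insensitive", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_plant_fixture(path, rows = c(
    "P1\tA\tTagetes\terecta\tanti-oxidant\tC1",
    "P2\tA\tTAGETES\tErecta\tanti-aging\tC2",
    "P3\tA\tTagetes\tlucida\t\tC3"))
  merged <- merge_species(read_plant_table(path))
  expect_equal(nrow(merged), 2)
  expect_equal(merged$activities[[1]], c("AOX", "AAG"))
  expect_setequal(merged$compound_ids[[1]], c("C1", "C2"))
})

test_that("fingerprint hex serialisation round-trips and checks lengths", {
  # hand-decoded prefix: "f0" = bits 1-4 set, bits 5-8 clear (MSB first)
  fp <- hex_to_fp(paste0("f0", strrep("0", 254)), 1024)
  expect_equal(which(as.integer(fp) == 1), 1:4)
  expect_equal(fp_popcount(fp), 4)
  expect_error(hex_to_fp(strrep("a", 100), 1024), "400")

  withr::with_seed(11, {
    for (i in 1:5) {
      bits <- as.integer(runif(1024) < 0.15)
      fp <- fingerprint(bits)
      expect_equal(as.integer(hex_to_fp(fp_to_hex(fp), 1024)), bits)
    }
  })
})

test_that("compound table reader types, range-checks and decodes", {
  tab <- compound_fixture(4)
  tab$targets[[2]] <- c("TP53", "IL6")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_table(tab, path)
  back <- read_compound_table(path)
  expect_equal(back$compound_id, tab$compound_id)
  expect_equal(back$MW, tab$MW, tolerance = 1e-12)
  expect_equal(back$targets[[2]], c("TP53", "IL6"))
  for (i in 1:4) {
    expect_equal(as.integer(back$fingerprint[[i]]),
                 as.integer(tab$fingerprint[[i]]))
  }

  bad <- tab
  bad$HBA[1] <- -1
  write_table(bad, path)
  expect_error(read_compound_table(path), "HBA")

  nofp <- tab[, setdiff(names(tab), "fingerprint")]
  write_table(nofp, path)
  back2 <- read_compound_table(path)
  expect_true(all(vapply(back2$fingerprint, is.null, logical(1))))
})

test_that("GMT parsing enforces the 3-field contract and set semantics", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("pw1\tfirst pathway\tTP53\tIL6\til6",
               "pw2\tsecond pathway\tEGFR\tTNF\tTP53"), path)
  db <- read_gmt(path)
  expect_equal(length(db), 2)
  expect_equal(db$pw1, c("TP53", "IL6"))  # dedup after case-folding
  expect_equal(attr(db, "pathway_names")[["pw2"]], "second pathway")

  writeLines(c("pw1\tok\tTP53", "pw2\tonlyname"), path)
  expect_error(read_gmt(path), "line 2")

  out <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(db, out)
  expect_equal(unclass(read_gmt(out)), unclass(db),
               ignore_attr = TRUE)
})

test_that("network writers round-trip the edge set in every format", {
  g <- igraph::make_ring(10)
  igraph::V(g)$name <- paste0("n", 1:10)
  igraph::V(g)$node_type <- "species"
  igraph::E(g)$relation <- "link"
  edge_key <- function(gr) {
    el <- igraph::as_edgelist(gr)
    sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2])))
  }
  for (fmt in c("sif", "graphml", "tsv")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_network(g, path, fmt)
    back <- read_network(path, fmt)
    expect_equal(edge_key(back), edge_key(g), info = fmt)
  }
})
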