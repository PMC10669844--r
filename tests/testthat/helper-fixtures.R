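# Programmatic fixtures: tiny tables and an SDF written at test time.

make_fp <- function(positions, length = 1024L) {
  fingerprint(positions, length = length, from_positions = TRUE)
}

write_plant_fixture <- function(path, rows = NULL) {
  header <- "plant_id\tfamily\tgenus\tspecies\tactivities\tcompounds"
  if (is.null(rows)) {
    rows <- c(
      "P1\tAsteraceae\tTagetes\terecta\tanti-oxidant;anti-aging\tC1;C2",
      "P2\tFabaceae\tLonchocarpus\tguatemalensis\t\tC2;C3",
      "P3\tAsteraceae\tTagetes\tlucida\tAnti-Inflammatory\tC1"
    )
  }
  writeLines(c(header, rows), path)
  path
}

compound_fixture <- function(n = 4, seed = 42) {
  withr::with_seed(seed, {
    tibble::tibble(
      compound_id = sprintf("C%d", seq_len(n)),
      name = sprintf("compound %d", seq_len(n)),
      MW = stats::runif(n, 150, 500),
      ALOGP = stats::rnorm(n, 2, 1),
      HBA = stats::rpois(n, 4),
      HBD = stats::rpois(n, 2),
      PSA = stats::runif(n, 20, 140),
      ROTB = stats::rpois(n, 4),
      AROM = stats::rpois(n, 1),
      ALERTS = stats::rpois(n, 0.3),
      fingerprint = lapply(seq_len(n), function(i) {
        fingerprint(as.integer(stats::runif(1024) < 0.1))
      }),
      mutagenic = FALSE, tumorigenic = FALSE, irritant = FALSE,
      reproductive = FALSE,
      targets = rep(list(character(0)), n),
      is_reference = FALSE,
      known_activities = rep(list(character(0)), n)
    )
  })
}

# three-molecule SDF (benzene, aspirin, ethanol), 2-D coordinates
sdf_fixture_text <- function() {
  benzene <- c(
    "benzene", " test 2D", "",
    "  6  6  0  0  0  0  0  0  0  0999 V2000",
    "   -0.8660   -0.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "   -1.7321   -0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "   -1.7321    1.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "   -0.8660    1.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "   -0.0000    1.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "  1  6  2  0  0  0  0", "  1  2  1  0  0  0  0", "  2  3  2  0  0  0  0",
    "  3  4  1  0  0  0  0", "  4  5  2  0  0  0  0", "  5  6  1  0  0  0  0",
    "M  END", "$$$$")
  ethanol <- c(
    "ethanol", " test 2D", "",
    "  3  2  0  0  0  0  0  0  0  0999 V2000",
    "    1.7321   -0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    0.8660    0.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "   -0.0000   -0.0000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0",
    "  1  2  1  0  0  0  0", "  2  3  1  0  0  0  0",
    "M  END", "$$$$")
  phenol <- c(
    "phenol", " test 2D", "",
    "  7  7  0  0  0  0  0  0  0  0999 V2000",
    "   -0.8660   -0.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "   -1.7321   -0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "   -1.7321    1.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "   -0.8660    1.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "   -0.0000    1.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    0.8660   -0.5000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0",
    "  1  6  2  0  0  0  0", "  1  2  1  0  0  0  0", "  2  3  2  0  0  0  0",
    "  3  4  1  0  0  0  0", "  4  5  2  0  0  0  0", "  5  6  1  0  0  0  0",
    "  6  7  1  0  0  0  0",
    "M  END", "$$$$")
  list(benzene = benzene, ethanol = ethanol, phenol = phenol)
}

write_sdf_fixture <- function(path, corrupt_second = FALSE) {
  blocks <- sdf_fixture_text()
  if (corrupt_second) {
    # claim 5 atoms but supply 3: the molblock cannot be parsed
    blocks$ethanol[4] <- "  5  2  0  0  0  0  0  0  0  0999 V2000"
  }
  writeLines(unlist(blocks), path)
  path
}

random_labels <- function(n, K) {
  # at least one point per cluster
  base <- rep(seq_len(K), length.out = n)
  sample(base)
}
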