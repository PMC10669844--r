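# SDF ingestion sits on ChemmineR/ChemmineOB (OpenBabel): structure parsing,
# physicochemical properties and the 1024-bit FP2 path fingerprint.

# Loose rotatable-bond SMARTS: any single, acyclic bond between two
# non-terminal atoms not involved in a triple bond.
ROTB_SMARTS <- "[!$(*#*)&!D1]-!@[!$(*#*)&!D1]"

#' Build a compound table from an SDF file
#'
#' Reads a V2000/V3000 SDF, drops molblocks that fail to parse (reported in
#' the `skipped` attribute, mirroring availability drops in curated
#' collections), and computes the eight QED descriptors plus a 1024-bit FP2
#' fingerprint per molecule.  Structural-alert counts are 0 unless an alert
#' SMARTS list is supplied; toxicity flags are left `FALSE` (supply them
#' precomputed via the compound table instead, or derive them from
#' `alert_smarts` hits).
#'
#' @param path SDF file path.
#' @param alert_smarts Optional named character vector of SMARTS patterns;
#'   `ALERTS` counts how many patterns match each molecule.
#' @return Compound tibble in the [read_compound_table()] layout, with
#'   attribute `skipped` (integer indices of unparsable molblocks).
#' @export
compounds_from_sdf <- function(path, alert_smarts = NULL) {
  if (!requireNamespace("ChemmineR", quietly = TRUE) ||
      !requireNamespace("ChemmineOB", quietly = TRUE)) {
    stop("compounds_from_sdf() needs the ChemmineR and ChemmineOB packages")
  }
  if (!file.exists(path)) stop("cannot read SDF file: ", path)
  sdf <- suppressWarnings(ChemmineR::read.SDFset(path))
  ok <- ChemmineR::validSDF(sdf)
  skipped <- as.integer(which(!ok))
  if (length(skipped) > 0) {
    message(length(skipped), " molblock(s) failed to parse and were skipped: ",
            paste(skipped, collapse = ", "))
  }
  sdf <- sdf[ok]
  if (length(sdf) == 0) {
    warning("no parsable molecules in ", path)
    out <- empty_compound_table()
    attr(out, "skipped") <- skipped
    return(out)
  }
  props <- ChemmineR::propOB(sdf)
  ring <- ChemmineR::rings(sdf, type = "count", arom = TRUE)
  rotb <- ChemmineR::smartsSearchOB(sdf, ROTB_SMARTS, uniqueMatches = FALSE)
  alerts <- rep(0L, length(sdf))
  if (!is.null(alert_smarts)) {
    for (pat in alert_smarts) {
      alerts <- alerts +
        as.integer(ChemmineR::smartsSearchOB(sdf, pat,
                                              uniqueMatches = FALSE) > 0)
    }
  }
  fps <- ChemmineR::fingerprintOB(sdf, "FP2")
  fp_list <- lapply(seq_along(sdf), function(i) {
    fingerprint(as.integer(fps[[i]]@fp))
  })
  titles <- props$title
  ids <- ChemmineR::sdfid(sdf)
  nm <- ifelse(nzchar(titles), titles, ids)
  n <- length(sdf)
  out <- tibble::tibble(
    compound_id = make.unique(ids),
    name = nm,
    MW = props$MW,
    ALOGP = props$logP,
    HBA = as.integer(props$HBA2),
    HBD = as.integer(props$HBD),
    PSA = props$TPSA,
    ROTB = as.integer(rotb) %/% 2L,   # SMARTS matches are directed pairs
    AROM = as.integer(ring[, "AROMATIC"]),
    ALERTS = alerts,
    fingerprint = fp_list,
    mutagenic = FALSE, tumorigenic = FALSE, irritant = FALSE,
    reproductive = FALSE,
    targets = rep(list(character(0)), n),
    is_reference = FALSE,
    known_activities = rep(list(character(0)), n)
  )
  attr(out, "skipped") <- skipped
  out
}

empty_compound_table <- function() {
  tibble::tibble(
    compound_id = character(0), name = character(0),
    MW = numeric(0), ALOGP = numeric(0), HBA = integer(0), HBD = integer(0),
    PSA = numeric(0), ROTB = integer(0), AROM = integer(0), ALERTS = integer(0),
    fingerprint = list(), mutagenic = logical(0), tumorigenic = logical(0),
    irritant = logical(0), reproductive = logical(0), targets = list(),
    is_reference = logical(0), known_activities = list()
  )
}
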