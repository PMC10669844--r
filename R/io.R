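#' Read a curated plant table
#'
#' Expects a delimited text file with header and mandatory columns
#' `plant_id`, `family`, `genus`, `species`, `activities`, `compounds`.
#' `activities` and `compounds` hold multi-value cells separated by
#' `multi_sep`.  Activity tokens are normalised case-insensitively onto the
#' four canonical classes via the vocabulary; unrecognised tokens are kept in
#' `other_annotations`.  Any extra columns are folded into
#' `other_annotations` as `"column=value"` strings.
#'
#' @param path File path.
#' @param delim Field delimiter (tab by default).
#' @param multi_sep Separator inside multi-value cells.
#' @param vocab Activity vocabulary, see [activity_vocab()].
#' @return Tibble with one row per plant: `plant_id`, `family`, `genus`,
#'   `species`, list-columns `activities` and `compound_ids`, logical
#'   `has_evidence`, list-column `other_annotations`.
#' @export
read_plant_table <- function(path, delim = "\t", multi_sep = ";",
                             vocab = activity_vocab()) {
  raw <- utils::read.delim(path, sep = delim, stringsAsFactors = FALSE,
                           check.names = FALSE, colClasses = "character")
  mandatory <- c("plant_id", "family", "genus", "species", "activities",
                 "compounds")
  missing <- setdiff(mandatory, names(raw))
  if (length(missing) > 0) {
    stop("plant table is missing mandatory column(s): ",
         paste(missing, collapse = ", "))
  }
  if (anyDuplicated(raw$plant_id)) {
    dup <- unique(raw$plant_id[duplicated(raw$plant_id)])
    stop("duplicate plant_id: ", paste(dup, collapse = ", "))
  }
  for (col in c("family", "genus", "species")) {
    bad <- which(!nzchar(trimws(raw[[col]])))
    if (length(bad) > 0) {
      stop(sprintf("empty %s at row %d", col, bad[1]))
    }
  }
  extra_cols <- setdiff(names(raw), mandatory)
  split_multi <- function(x) {
    if (is.na(x) || !nzchar(trimws(x))) character(0)
    else trimws(strsplit(x, multi_sep, fixed = TRUE)[[1]])
  }
  n <- nrow(raw)
  activities <- vector("list", n)
  annotations <- vector("list", n)
  compound_ids <- vector("list", n)
  for (i in seq_len(n)) {
    norm <- normalize_activities(split_multi(raw$activities[i]), vocab)
    activities[[i]] <- norm$activities
    compound_ids[[i]] <- unique(split_multi(raw$compounds[i]))
    extras <- character(0)
    if (length(norm$unknown) > 0) {
      extras <- paste0("activity_token=", norm$unknown)
    }
    for (col in extra_cols) {
      val <- raw[[col]][i]
      if (!is.na(val) && nzchar(trimws(val))) {
        extras <- c(extras, paste0(col, "=", trimws(val)))
      }
    }
    annotations[[i]] <- extras
  }
  tibble::tibble(
    plant_id = raw$plant_id,
    family = trimws(raw$family),
    genus = trimws(raw$genus),
    species = trimws(raw$species),
    activities = activities,
    has_evidence = lengths(activities) > 0,
    compound_ids = compound_ids,
    other_annotations = annotations
  )
}

#' Merge synonymous species rows
#'
#' Species identity is the (genus, species) pair, case-insensitive; an
#' optional synonym map (named character vector `old_name = accepted_name`,
#' names as `"genus species"`) is applied first.  Merged rows take the first
#' `plant_id` and the union of activities, compounds and annotations.
#'
#' @param plants Plant tibble from [read_plant_table()].
#' @param synonyms Optional named character vector of `"genus species"` keys.
#' @return Plant tibble with one row per accepted species.
#' @export
merge_species <- function(plants, synonyms = NULL) {
  key <- tolower(paste(plants$genus, plants$species))
  if (!is.null(synonyms)) {
    hit <- match(key, tolower(names(synonyms)))
    key[!is.na(hit)] <- tolower(synonyms[hit[!is.na(hit)]])
  }
  idx <- split(seq_len(nrow(plants)), factor(key, levels = unique(key)))
  merged <- lapply(idx, function(rows) {
    first <- plants[rows[1], ]
    first$activities <- list(ACTIVITY_CLASSES[
      ACTIVITY_CLASSES %in% unique(unlist(plants$activities[rows]))])
    first$compound_ids <- list(unique(unlist(plants$compound_ids[rows])))
    first$other_annotations <- list(unique(unlist(plants$other_annotations[rows])))
    first$has_evidence <- length(first$activities[[1]]) > 0
    first
  })
  dplyr::bind_rows(merged)
}

#' Read a compound table
#'
#' Mandatory columns: `compound_id`, `name`, and the eight QED descriptors
#' `MW`, `ALOGP`, `HBA`, `HBD`, `PSA`, `ROTB`, `AROM`, `ALERTS`.  Optional:
#' `fingerprint` (lowercase hex or 0/1 bitstring of `fp_length` bits),
#' toxicity flags `mutagenic`/`tumorigenic`/`irritant`/`reproductive`
#' (logical or 0/1), `targets` (multi-value gene symbols), `is_reference`,
#' and `known_activities` (free-text activity tokens).
#'
#' @inheritParams read_plant_table
#' @param fp_length Declared fingerprint length.
#' @return Tibble with typed descriptor columns, logical flag columns,
#'   list-columns `fingerprint` (integer 0/1 vectors or `NULL`), `targets`
#'   and `known_activities`.
#' @export
read_compound_table <- function(path, delim = "\t", multi_sep = ";",
                                fp_length = 1024L, vocab = activity_vocab()) {
  raw <- utils::read.delim(path, sep = delim, stringsAsFactors = FALSE,
                           check.names = FALSE, colClasses = "character")
  mandatory <- c("compound_id", "name", QED_DESCRIPTORS)
  missing <- setdiff(mandatory, names(raw))
  if (length(missing) > 0) {
    stop("compound table is missing mandatory column(s): ",
         paste(missing, collapse = ", "))
  }
  if (anyDuplicated(raw$compound_id)) {
    stop("duplicate compound_id: ",
         paste(unique(raw$compound_id[duplicated(raw$compound_id)]),
               collapse = ", "))
  }
  n <- nrow(raw)
  out <- tibble::tibble(compound_id = raw$compound_id, name = raw$name)
  for (col in QED_DESCRIPTORS) {
    val <- suppressWarnings(as.numeric(raw[[col]]))
    if (anyNA(val)) stop(sprintf("non-numeric %s at row %d", col,
                                 which(is.na(val))[1]))
    out[[col]] <- val
  }
  check_descriptor_ranges(out)
  count_cols <- c("HBA", "HBD", "ROTB", "AROM", "ALERTS")
  for (col in count_cols) out[[col]] <- as.integer(round(out[[col]]))

  out$fingerprint <- rep(list(NULL), n)
  if ("fingerprint" %in% names(raw)) {
    out$fingerprint <- lapply(seq_len(n), function(i) {
      s <- trimws(raw$fingerprint[i])
      if (is.na(s) || !nzchar(s)) return(NULL)
      if (grepl("^[01]+$", s) && nchar(s) > fp_length / 4) {
        if (nchar(s) != fp_length) {
          stop(sprintf("row %d: bitstring length %d != declared length %d",
                       i, nchar(s), fp_length))
        }
        fingerprint(as.integer(strsplit(s, "")[[1]]))
      } else {
        hex_to_fp(s, fp_length)
      }
    })
  }
  flag_cols <- c("mutagenic", "tumorigenic", "irritant", "reproductive")
  for (col in flag_cols) {
    out[[col]] <- if (col %in% names(raw)) parse_flag(raw[[col]], col)
                  else rep(FALSE, n)
  }
  split_multi <- function(x) {
    if (is.na(x) || !nzchar(trimws(x))) character(0)
    else trimws(strsplit(x, multi_sep, fixed = TRUE)[[1]])
  }
  out$targets <- if ("targets" %in% names(raw)) {
    lapply(raw$targets, function(x) unique(toupper(split_multi(x))))
  } else rep(list(character(0)), n)
  out$is_reference <- if ("is_reference" %in% names(raw)) {
    parse_flag(raw$is_reference, "is_reference")
  } else rep(FALSE, n)
  out$known_activities <- if ("known_activities" %in% names(raw)) {
    lapply(raw$known_activities,
           function(x) normalize_activities(split_multi(x), vocab)$activities)
  } else rep(list(character(0)), n)
  no_fp <- out$is_reference & vapply(out$fingerprint, is.null, logical(1))
  if (any(no_fp)) {
    stop("reference compound(s) without fingerprint: ",
         paste(out$compound_id[no_fp], collapse = ", "))
  }
  out
}

parse_flag <- function(x, col) {
  v <- tolower(trimws(x))
  out <- v %in% c("true", "t", "1", "yes")
  bad <- !(v %in% c("true", "t", "1", "yes", "false", "f", "0", "no", "", "na"))
  if (any(bad)) stop(sprintf("non-boolean %s at row %d", col, which(bad)[1]))
  out
}

check_descriptor_ranges <- function(tab) {
  if (any(tab$MW <= 0)) {
    stop("MW must be positive (row ", which(tab$MW <= 0)[1], ")")
  }
  if (any(tab$PSA < 0)) {
    stop("PSA must be nonnegative (row ", which(tab$PSA < 0)[1], ")")
  }
  for (col in c("HBA", "HBD", "ROTB", "AROM", "ALERTS")) {
    if (any(tab[[col]] < 0)) {
      stop(col, " must be a nonnegative count (row ",
           which(tab[[col]] < 0)[1], ")")
    }
  }
  invisible(tab)
}

#' Write a table as delimited text
#'
#' List-columns are flattened with `multi_sep`; fingerprint list-columns are
#' hex-encoded.  Inverse of the package readers for the supported fields.
#'
#' @param tab Tibble or data frame.
#' @param path Output path.
#' @param delim Field delimiter.
#' @param multi_sep Separator for multi-value cells.
#' @export
write_table <- function(tab, path, delim = "\t", multi_sep = ";") {
  flat <- as.data.frame(lapply(tab, function(col) {
    if (is.list(col)) {
      vapply(col, function(x) {
        if (is.null(x) || length(x) == 0) ""
        else if (inherits(x, "fingerprint")) fp_to_hex(x)
        else paste(x, collapse = multi_sep)
      }, character(1))
    } else col
  }), check.names = FALSE)
  utils::write.table(flat, path, sep = delim, quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' Each line is `id<TAB>name<TAB>gene1<TAB>gene2...`.  Genes are upper-cased
#' and de-duplicated within a set.
#'
#' @param path GMT file path.
#' @return A `pathway_db`: named list of character gene sets with a
#'   `pathway_names` attribute carrying the display names.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short) > 0) {
    stop(sprintf("GMT line %d has %d field(s); at least 3 required",
                 short[1], lengths(fields)[short[1]]))
  }
  ids <- vapply(fields, `[`, character(1), 1)
  if (anyDuplicated(ids)) {
    stop("duplicate pathway id: ", ids[duplicated(ids)][1])
  }
  sets <- lapply(fields, function(f) unique(toupper(f[-c(1, 2)])))
  if (any(lengths(sets) == 0)) stop("empty gene set: ",
                                    ids[lengths(sets) == 0][1])
  names(sets) <- ids
  structure(sets, pathway_names = stats::setNames(
    vapply(fields, `[`, character(1), 2), ids), class = "pathway_db")
}

#' Write gene sets in GMT format
#' @param db `pathway_db` from [read_gmt()] or a named list of gene sets.
#' @param path Output path.
#' @export
write_gmt <- function(db, path) {
  nm <- attr(db, "pathway_names")
  if (is.null(nm)) nm <- stats::setNames(names(db), names(db))
  lines <- vapply(names(db), function(id) {
    paste(c(id, nm[[id]], db[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Export a network
#'
#' @param graph An igraph object (node attribute `name` required; `node_type`
#'   and edge attribute `relation` used when present).
#' @param path Output path.
#' @param format `"sif"` (`source<TAB>relation<TAB>target`), `"graphml"`, or
#'   `"tsv"` (edge list with optional relation column).
#' @export
write_network <- function(graph, path, format = c("sif", "graphml", "tsv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(graph, path, format = "graphml")
    return(invisible(path))
  }
  el <- igraph::as_edgelist(graph)
  rel <- if ("relation" %in% igraph::edge_attr_names(graph)) {
    igraph::E(graph)$relation
  } else rep("link", nrow(el))
  df <- data.frame(source = el[, 1], relation = rel, target = el[, 2],
                   stringsAsFactors = FALSE)
  if (format == "tsv") df <- df[, c("source", "target", "relation")]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = (format == "tsv"))
  invisible(path)
}

#' Read a network written by [write_network()]
#' @param path File path.
#' @param format `"sif"`, `"graphml"` or `"tsv"`.
#' @return igraph object.
#' @export
read_network <- function(path, format = c("sif", "graphml", "tsv")) {
  format <- match.arg(format)
  if (format == "graphml") return(igraph::read_graph(path, format = "graphml"))
  df <- utils::read.delim(path, header = (format == "tsv"),
                          stringsAsFactors = FALSE)
  if (format == "sif") names(df) <- c("source", "relation", "target")
  g <- igraph::graph_from_data_frame(df[, c("source", "target")],
                                     directed = FALSE)
  igraph::E(g)$relation <- df$relation
  g
}
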