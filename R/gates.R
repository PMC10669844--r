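#' Toxicity flag names
#' @export
TOX_FLAGS <- c("mutagenic", "tumorigenic", "irritant", "reproductive")

#' Toxicity-alert gate
#'
#' Splits compounds into those free of every considered alert flag and those
#' carrying at least one.  Only the flags listed in `flags_considered` count;
#' the default considers all four (the conservative union screen).
#'
#' @param compounds Compound tibble with logical flag columns (see
#'   [read_compound_table()]).
#' @param flags_considered Subset of [TOX_FLAGS].
#' @return List with tibbles `clean` and `flagged` partitioning the input.
#' @export
toxicity_gate <- function(compounds, flags_considered = TOX_FLAGS) {
  stopifnot(all(flags_considered %in% TOX_FLAGS))
  if (length(flags_considered) == 0) {
    return(list(clean = compounds, flagged = compounds[0, ]))
  }
  flag_mat <- as.matrix(compounds[, flags_considered, drop = FALSE])
  hit <- rowSums(flag_mat) > 0
  list(clean = compounds[!hit, ], flagged = compounds[hit, ])
}

#' Target-availability gate
#'
#' Keeps compounds with at least one reported pharmacological target gene.
#'
#' @param compounds Compound tibble with a `targets` list-column.
#' @return List with tibbles `with_targets` and `without_targets`.
#' @export
target_gate <- function(compounds) {
  has <- lengths(compounds$targets) > 0
  list(with_targets = compounds[has, ], without_targets = compounds[!has, ])
}
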