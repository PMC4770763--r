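EVIDENCE_LEVELS <- c("low_throughput", "high_throughput")

#' Read a miRNA-target interaction table
#'
#' Reads a tab-separated table of experimentally verified miRNA-target
#' interactions in the style of miRTarBase/TarBase/miRecords exports.
#' Rows with a missing miRNA or target id, or an unrecognized evidence
#' class, are dropped and counted in a message (the readers never abort
#' on dirty rows).  Duplicate rows are retained; see
#' [deduplicate_interactions()].
#'
#' @param path Path to a delimited text file with a header row.
#' @param columns Named character vector mapping the canonical column
#'   roles `mirna`, `target`, `species`, `evidence`, `source` to the
#'   column names used in the file.
#' @param sep Field separator (default tab).
#' @return A data frame with columns `mirna`, `target`, `species`,
#'   `evidence` (one of `"low_throughput"`, `"high_throughput"`) and
#'   `source`.
#' @export
read_interactions <- function(path,
                              columns = c(mirna = "mirna", target = "target",
                                          species = "species",
                                          evidence = "evidence",
                                          source = "source"),
                              sep = "\t") {
  required <- c("mirna", "target", "species", "evidence", "source")
  if (!all(required %in% names(columns))) {
    stop("'columns' must name all of: ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  tab <- read.delim(path, sep = sep, stringsAsFactors = FALSE, quote = "",
                    comment.char = "", colClasses = "character",
                    na.strings = NULL)
  missing <- setdiff(unname(columns[required]), names(tab))
  if (length(missing)) {
    stop("interaction table '", path, "' is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- data.frame(mirna = trimws(tab[[columns[["mirna"]]]]),
                    target = trimws(tab[[columns[["target"]]]]),
                    species = trimws(tab[[columns[["species"]]]]),
                    evidence = tolower(trimws(tab[[columns[["evidence"]]]])),
                    source = trimws(tab[[columns[["source"]]]]),
                    stringsAsFactors = FALSE)
  n0 <- nrow(out)
  keep <- nzchar(out$mirna) & nzchar(out$target)
  n_empty <- sum(!keep)
  out <- out[keep, , drop = FALSE]
  ok_ev <- out$evidence %in% EVIDENCE_LEVELS
  n_badev <- sum(!ok_ev)
  out <- out[ok_ev, , drop = FALSE]
  if (n_empty + n_badev > 0) {
    message("read_interactions: dropped ", n_empty,
            " row(s) with missing miRNA/target and ", n_badev,
            " row(s) with unrecognized evidence (", n0, " rows read)")
  }
  rownames(out) <- NULL
  out
}

#' Collapse duplicate miRNA-target interaction records
#'
#' Redundancy processing across source databases: records are collapsed
#' to one per `(mirna, target, species)` key.  The merged record is
#' `low_throughput` if any duplicate carried low-throughput evidence
#' (small-scale validation trumps high-throughput screens), and its
#' `source` field is the semicolon-joined union of the duplicate
#' sources.  The operation is idempotent and returns rows sorted by key
#' so the output is deterministic.
#'
#' @param records Interaction data frame as from [read_interactions()].
#' @return Deduplicated interaction data frame.
#' @export
deduplicate_interactions <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("mirna", "target", "species", "evidence", "source")
                %in% names(records)))
  if (!nrow(records)) return(records)
  key <- paste(records$mirna, records$target, records$species, sep = "\r")
  idx <- split(seq_len(nrow(records)), key)
  rows <- lapply(idx, function(i) {
    data.frame(mirna = records$mirna[i[1]],
               target = records$target[i[1]],
               species = records$species[i[1]],
               evidence = if (any(records$evidence[i] == "low_throughput"))
                 "low_throughput" else "high_throughput",
               source = paste(sort(unique(unlist(
                 strsplit(records$source[i], ";", fixed = TRUE)))),
                 collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out <- out[order(out$mirna, out$target, out$species), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Keep low-throughput interactions for one species
#'
#' Restricts a deduplicated interaction table to records supported by
#' low-throughput (small-scale) experiments in the given organism; only
#' these high-confidence edges are embedded into pathway graphs.
#'
#' @param records Deduplicated interaction data frame.
#' @param species Organism code (one of [SPECIES_CODES]).
#' @return Filtered interaction data frame (possibly zero rows).
#' @export
filter_low_throughput <- function(records, species) {
  check_species(species)
  keep <- records$evidence == "low_throughput" & records$species == species
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a precursor-to-mature miRNA mapping table
#'
#' @param path Two-column tab-separated file (precursor id, mature id),
#'   one pair per row, with a header row.
#' @return A named list mapping each precursor id to a character vector
#'   of mature ids.
#' @export
read_precursor_map <- function(path) {
  tab <- read.delim(path, sep = "\t", stringsAsFactors = FALSE, quote = "",
                    comment.char = "", colClasses = "character",
                    na.strings = NULL)
  if (ncol(tab) < 2) {
    stop("precursor map '", path, "' must have two columns", call. = FALSE)
  }
  pre <- trimws(tab[[1]]); mat <- trimws(tab[[2]])
  keep <- nzchar(pre) & nzchar(mat)
  lapply(split(mat[keep], pre[keep]), function(x) sort(unique(x)))
}

#' Convert precursor miRNA ids to mature ids
#'
#' Differential miRNA calls are often made at the precursor (pre-miRNA)
#' level while interaction tables use mature names; this expands each
#' precursor to all of its mature forms.  Precursors absent from the
#' mapping are reported in the `unmapped` element rather than silently
#' dropped.
#'
#' @param mirna_ids Character vector of precursor ids.
#' @param pmap Mapping as from [read_precursor_map()].
#' @return A list with elements `mature` (sorted unique mature ids) and
#'   `unmapped` (sorted precursor ids with no mapping).
#' @export
map_precursors <- function(mirna_ids, pmap) {
  mirna_ids <- unique(as.character(mirna_ids))
  stopifnot(is.list(pmap))
  hit <- mirna_ids %in% names(pmap)
  list(mature = sort(unique(as.character(
         unlist(pmap[mirna_ids[hit]], use.names = FALSE)))),
       unmapped = sort(mirna_ids[!hit]))
}
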