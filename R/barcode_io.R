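# Reading/writing FASTA + manifests, dataset assembly, the minimum-count
# species filter, and integer label encoding.

#' Read barcode sequences from a FASTA file
#'
#' Reads a (possibly multi-line wrapped) FASTA file into a data frame of
#' barcode records. The species of each record is taken from `manifest`
#' when supplied; otherwise a `|species=<name>` token in the FASTA header
#' is used as a fallback. Records without a species from either source get
#' `NA` and are rejected by downstream dataset assembly.
#'
#' @param path Path to a FASTA file.
#' @param manifest Optional manifest data frame as returned by
#'   [read_manifest()], authoritative for species names.
#' @return A data frame with columns `record_id`, `species`, `sequence`
#'   (uppercase), one row per FASTA entry, input order preserved.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">r1 |species=Termitomyces heimii", "ACGTACGT",
#'              ">r2 |species=Termitomyces heimii", "ttggcc"), fa)
#' read_fasta(fa)
read_fasta <- function(path, manifest = NULL) {
  stopifnot(file.exists(path))
  if (file.size(path) == 0L) {
    return(data.frame(record_id = character(0), species = character(0),
                      sequence = character(0), stringsAsFactors = FALSE))
  }
  ss <- Biostrings::readBStringSet(path)
  headers <- names(ss)
  ids <- vapply(strsplit(headers, "[ \t|]"), `[`, character(1), 1L)
  if (anyNA(ids) || any(!nzchar(ids))) {
    stop("FASTA entry with empty ID at position ",
         which(is.na(ids) | !nzchar(ids))[1])
  }
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA record ID: ", ids[duplicated(ids)][1])
  }
  seqs <- toupper(as.character(ss))
  empty <- !nzchar(seqs)
  if (any(empty)) stop("empty sequence for record: ", ids[empty][1])
  species <- species_from_headers(headers)
  if (!is.null(manifest)) {
    hit <- match(ids, manifest$record_id)
    species <- ifelse(is.na(hit), species, manifest$species[hit])
  }
  data.frame(record_id = unname(ids), species = unname(species),
             sequence = unname(seqs), stringsAsFactors = FALSE)
}

# `|species=Genus epithet` header token; underscores stand for spaces
species_from_headers <- function(headers) {
  m <- regmatches(headers, regexpr("\\|species=[^|]+", headers))
  out <- rep(NA_character_, length(headers))
  has <- grepl("\\|species=", headers)
  out[has] <- trimws(sub("^\\|species=", "", m))
  gsub("_", " ", out)
}

#' Write barcode records to a FASTA file
#'
#' Headers carry the record ID and a `|species=` token (spaces encoded as
#' underscores) so that [read_fasta()] round-trips records losslessly.
#'
#' @param records Data frame with `record_id`, `species`, `sequence`.
#' @param path Output path.
#' @param width Line-wrap width for sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  ss <- Biostrings::BStringSet(records$sequence)
  names(ss) <- paste0(records$record_id, " |species=",
                      gsub(" ", "_", records$species))
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Read a dataset manifest (TSV)
#'
#' The manifest maps record IDs to species names and sequence sources.
#' Expected header: `record_id<TAB>species<TAB>source` (optional `length`).
#'
#' @param path Path to a tab-separated manifest.
#' @return Data frame with at least `record_id`, `species`, `source`.
#' @export
read_manifest <- function(path) {
  stopifnot(file.exists(path))
  m <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("record_id", "species")
  missing <- setdiff(need, names(m))
  if (length(missing)) {
    stop("manifest is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (!"source" %in% names(m)) m$source <- "other"
  if (anyDuplicated(m$record_id)) {
    stop("manifest has duplicate record_id: ",
         m$record_id[duplicated(m$record_id)][1])
  }
  if (any(is.na(m$species) | !nzchar(m$species))) {
    stop("manifest has empty species for record: ",
         m$record_id[is.na(m$species) | !nzchar(m$species)][1])
  }
  m
}

#' Write a dataset manifest (TSV)
#'
#' @param records Data frame with `record_id` and `species`; a `source`
#'   column is added as `"other"` when absent.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(records, path) {
  m <- records[, intersect(c("record_id", "species", "source"),
                           names(records)), drop = FALSE]
  if (!"source" %in% names(m)) m$source <- "other"
  write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read FASTA + manifest into labeled records
#'
#' Convenience wrapper: reads the FASTA, attaches manifest species, and
#' deduplicates exact (species, sequence) pairs that occur when the same
#' barcode is deposited in more than one repository.
#'
#' @param fasta Path to FASTA file.
#' @param manifest Optional path to a manifest TSV.
#' @param dedup Drop later records whose (species, sequence) pair was
#'   already seen. Default `TRUE`.
#' @return Record data frame (`record_id`, `species`, `sequence`).
#' @export
read_barcodes <- function(fasta, manifest = NULL, dedup = TRUE) {
  man <- if (!is.null(manifest)) read_manifest(manifest) else NULL
  rec <- read_fasta(fasta, manifest = man)
  if (any(is.na(rec$species))) {
    stop("no species for record(s): ",
         paste(head(rec$record_id[is.na(rec$species)], 3), collapse = ", "),
         " (provide a manifest or |species= header tokens)")
  }
  if (dedup) rec <- rec[!duplicated(paste0(rec$species, "\r", rec$sequence)), ]
  rownames(rec) <- NULL
  rec
}

#' Encode species names as integer labels
#'
#' Assigns codes `0..S-1` by case-sensitive byte-order (C-locale)
#' lexicographic sort of the verbatim species strings. This ordering puts
#' uppercase before lowercase, so e.g. a name with an uppercase strain tag
#' sorts ahead of ordinary lowercase epithets.
#'
#' @param species_names Character vector of species names (duplicates
#'   allowed; the distinct set is encoded).
#' @return Named integer vector: `label_map[species] -> code`.
#' @export
#' @examples
#' encode_labels(c("Termitomyces heimii", "Termitomyces clypeatus"))
encode_labels <- function(species_names) {
  sp <- unique(as.character(species_names))
  if (length(sp) == 0L) stop("at least one species is required")
  sp <- sort(sp, method = "radix")  # byte order, locale-independent
  setNames(seq_along(sp) - 1L, sp)
}

#' Filter species by minimum record count and assemble a dataset
#'
#' Species represented by fewer than `min_count` records are dropped
#' entirely; surviving records keep their input order and the label map is
#' rebuilt over the surviving species with [encode_labels()].
#'
#' @param records Record data frame (`record_id`, `species`, `sequence`).
#' @param min_count Minimum records per retained species (default 7).
#' @return A `barcode_dataset`: list with `records`, `label_map`,
#'   `min_count`.
#' @export
filter_min_count <- function(records, min_count = 7L) {
  stopifnot(min_count >= 0)
  validate_records(records)
  n_per <- table(records$species)
  keep <- names(n_per)[n_per >= min_count]
  out <- records[records$species %in% keep, , drop = FALSE]
  if (nrow(out) == 0L) {
    stop("empty dataset: every species has fewer than ", min_count,
         " records")
  }
  rownames(out) <- NULL
  structure(list(records = out,
                 label_map = encode_labels(out$species),
                 min_count = as.integer(min_count)),
            class = "barcode_dataset")
}

validate_records <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("record_id", "species", "sequence") %in% names(records)))
  if (nrow(records) == 0L) stop("no records")
  if (anyDuplicated(records$record_id)) {
    stop("duplicate record_id: ",
         records$record_id[duplicated(records$record_id)][1])
  }
  bad <- !nzchar(records$sequence) | grepl("[[:space:]]", records$sequence)
  if (any(bad)) {
    stop("empty or whitespace-containing sequence for record: ",
         records$record_id[bad][1])
  }
  invisible(records)
}

#' @export
print.barcode_dataset <- function(x, ...) {
  cat("<barcode_dataset> ", nrow(x$records), " records, ",
      length(x$label_map), " species (min_count=", x$min_count, ")\n",
      sep = "")
  invisible(x)
}

#' Per-species summary of a dataset
#'
#' One row per species with its integer code and record count, sorted by
#' label code — the layout of a training-set composition table.
#'
#' @param dataset A `barcode_dataset`.
#' @param path Optional TSV output path.
#' @return Data frame with `species`, `label`, `n_sequences`.
#' @export
dataset_summary <- function(dataset, path = NULL) {
  stopifnot(inherits(dataset, "barcode_dataset"))
  n <- table(dataset$records$species)
  out <- data.frame(species = names(dataset$label_map),
                    label = unname(dataset$label_map),
                    n_sequences = as.integer(n[names(dataset$label_map)]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (!is.null(path)) {
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}

# integer class vector (0..S-1) for the dataset's records
dataset_labels <- function(dataset) {
  unname(dataset$label_map[dataset$records$species])
}
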