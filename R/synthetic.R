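# Synthetic barcode generator: star phylogeny per species (one random
# ancestor, iid descendants mutated at a within-species substitution
# rate), with the long-tailed class-size imbalance typical of public
# barcode repositories.

#' Configuration for the synthetic barcode generator
#'
#' Each species gets an ancestor sequence drawn uniformly over ACGT with
#' length uniform in `length_range`; descendants are copies of the
#' ancestor with point substitutions at rate `within_noise` per base
#' (uniform among the three alternative bases) and, optionally, indels.
#' Ancestors are drawn independently, so two ancestors differ at roughly
#' 75% of positions; `between_divergence` optionally lowers that contrast
#' by deriving every ancestor from one root sequence mutated at the given
#' rate — the knob that makes species hard to separate.
#'
#' @param n_species Number of species.
#' @param counts Per-species record counts: an explicit integer vector
#'   (recycled to `n_species`) or `NULL` to sample log-uniformly over
#'   `[min_count, max_count]` (the long-tail profile).
#' @param length_range Ancestor length range in bases (default
#'   `c(200, 2000)`).
#' @param between_divergence Substitution fraction separating species
#'   ancestors from a common root; `NA` (default) draws independent
#'   ancestors.
#' @param within_noise Per-base substitution probability within a species
#'   (default 0.005).
#' @param indel_rate Per-base insertion/deletion probability (default 0,
#'   since the feature model is alignment-free).
#' @param min_count,max_count Bounds for the log-uniform count sampler.
#' @param seed Integer seed.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_species = 17L, counts = 20L,
                             length_range = c(200L, 2000L),
                             between_divergence = NA_real_,
                             within_noise = 0.005, indel_rate = 0,
                             min_count = 7L, max_count = 800L,
                             seed = 1L) {
  stopifnot(n_species >= 1L, within_noise >= 0, within_noise <= 1,
            indel_rate >= 0, indel_rate <= 1,
            length_range[1] >= 1L, length_range[2] >= length_range[1])
  if (!is.na(between_divergence)) {
    stopifnot(between_divergence >= 0, between_divergence <= 1)
    if (within_noise > between_divergence) {
      warning("within_noise exceeds between_divergence: species will ",
              "overlap (stress regime)", call. = FALSE)
    }
  }
  if (!is.null(counts)) {
    counts <- rep_len(as.integer(counts), n_species)
    stopifnot(all(counts >= 1L))
  }
  structure(list(n_species = as.integer(n_species), counts = counts,
                 length_range = as.integer(length_range),
                 between_divergence = between_divergence,
                 within_noise = within_noise, indel_rate = indel_rate,
                 min_count = as.integer(min_count),
                 max_count = as.integer(max_count),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' The empirical long-tail class-size profile
#'
#' A 17-species configuration whose per-class counts are the composition
#' of a curated Termitomyces ITS training corpus: 799, 483, 94, 60, 34,
#' 33, 30, 29, 24, 24, 17, 16, 15, 14, 12, 10, 10 sequences (1,704 in
#' total, smallest class 10).
#'
#' @param ... Overrides passed on to [synthetic_config()].
#' @return A `synthetic_config` with the fixed 17-class count vector.
#' @export
table2_profile <- function(...) {
  counts <- c(799L, 483L, 94L, 60L, 34L, 33L, 30L, 29L, 24L, 24L, 17L,
              16L, 15L, 14L, 12L, 10L, 10L)
  synthetic_config(n_species = 17L, counts = counts, ...)
}

mutate_sequence <- function(seq_chars, rate, indel_rate = 0) {
  bases <- c("A", "C", "G", "T")
  L <- length(seq_chars)
  n_sub <- rbinom(1L, L, rate)
  if (n_sub > 0L) {
    pos <- sample.int(L, n_sub)
    for (p in pos) {
      seq_chars[p] <- sample(setdiff(bases, seq_chars[p]), 1L)
    }
  }
  if (indel_rate > 0) {
    n_indel <- rbinom(1L, L, indel_rate)
    for (i in seq_len(n_indel)) {
      p <- sample.int(length(seq_chars), 1L)
      if (runif(1) < 0.5 && length(seq_chars) > 1L) {
        seq_chars <- seq_chars[-p]
      } else {
        seq_chars <- append(seq_chars, sample(bases, 1L), after = p)
      }
    }
  }
  seq_chars
}

#' Generate a labeled synthetic barcode dataset
#'
#' @param config A [synthetic_config()].
#' @return List with `dataset` (a `barcode_dataset`) and `truth` (list
#'   with per-species `ancestors` and a per-record `mutations` count).
#'   Species are named `Species_000`, `Species_001`, ...
#' @export
generate_dataset <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  bases <- c("A", "C", "G", "T")
  with_seed(config$seed, {
    counts <- config$counts
    if (is.null(counts)) {
      lo <- log(config$min_count)
      hi <- log(config$max_count)
      counts <- pmax(1L, as.integer(round(exp(runif(config$n_species,
                                                    lo, hi)))))
    }
    root <- NULL
    if (!is.na(config$between_divergence)) {
      # root at the maximum length; per-species prefix truncation keeps
      # length variation without disturbing the divergence structure
      root <- sample(bases, config$length_range[2], replace = TRUE)
    }
    ancestors <- vector("list", config$n_species)
    records <- vector("list", config$n_species)
    mutations <- vector("list", config$n_species)
    for (s in seq_len(config$n_species)) {
      # sample.int on the width: sample() misbehaves on scalar ranges
      L <- config$length_range[1] +
        sample.int(config$length_range[2] - config$length_range[1] + 1L,
                   1L) - 1L
      if (is.null(root)) {
        anc <- sample(bases, L, replace = TRUE)
      } else {
        anc <- mutate_sequence(root, config$between_divergence)[seq_len(L)]
      }
      ancestors[[s]] <- paste(anc, collapse = "")
      sp <- sprintf("Species_%03d", s - 1L)
      seqs <- character(counts[s])
      nmut <- integer(counts[s])
      for (r in seq_len(counts[s])) {
        mut <- mutate_sequence(anc, config$within_noise, config$indel_rate)
        seqs[r] <- paste(mut, collapse = "")
        nmut[r] <- sum(mut[seq_len(min(length(mut), length(anc)))] !=
                         anc[seq_len(min(length(mut), length(anc)))])
      }
      records[[s]] <- data.frame(
        record_id = sprintf("%s_rec%04d", sp, seq_len(counts[s])),
        species = sp, sequence = seqs, stringsAsFactors = FALSE)
      mutations[[s]] <- nmut
    }
  })
  rec <- do.call(rbind, records)
  rownames(rec) <- NULL
  dataset <- structure(list(records = rec,
                            label_map = encode_labels(rec$species),
                            min_count = 0L),
                       class = "barcode_dataset")
  names(ancestors) <- sprintf("Species_%03d", seq_len(config$n_species) - 1L)
  list(dataset = dataset,
       truth = list(ancestors = ancestors,
                    mutations = setNames(mutations, names(ancestors)),
                    config = config))
}

#' Write a synthetic dataset to FASTA + manifest (+ truth JSON)
#'
#' @param sim Output of [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_synthetic <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, "synthetic.fasta")
  manifest <- file.path(dir, "synthetic.manifest.tsv")
  truth <- file.path(dir, "synthetic.truth.json")
  write_fasta(sim$dataset$records, fasta)
  write_manifest(sim$dataset$records, manifest)
  cfg <- sim$truth$config
  jsonlite::write_json(list(ancestors = as.list(sim$truth$ancestors),
                            mutations = sim$truth$mutations,
                            config = unclass(cfg)),
                       truth, auto_unbox = TRUE, digits = NA)
  invisible(c(fasta = fasta, manifest = manifest, truth = truth))
}
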