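# Shared fixtures, all generated in code.

# the 17-species composition of the curated Termitomyces ITS corpus:
# verbatim names with their published integer codes and record counts
termitomyces_table <- function() {
  data.frame(
    species = c("Uncultured Termitomyces", "Termitomyces sp.",
                "Termitomyces intermedius", "Termitomyces symbiont",
                "Termitomyces microcarpus", "Termitomyces clypeatus",
                "Termitomyces cylindricus", "Termitomyces striatus",
                "Termitomyces DKA-2007", "Termitomyces heimii",
                "Termitomyces bulborhizus", "Termitomyces fuliginosus",
                "Termitomyces eurrhizus", "Termitomyces albuminosus",
                "Termitomyces sp. symbiont of Macrotermes bellicosus",
                "Termitomyces sp. symbiont of Macrotermes subhyalinus",
                "Uncultured Ascomycota"),
    label = c(16L, 10L, 8L, 14L, 9L, 3L, 4L, 13L, 0L, 7L, 2L, 6L, 5L,
              1L, 11L, 12L, 15L),
    n_sequences = c(799L, 483L, 94L, 60L, 34L, 33L, 30L, 29L, 24L, 24L,
                    17L, 16L, 15L, 14L, 12L, 10L, 10L),
    stringsAsFactors = FALSE)
}

# one tiny record per (species, count) expansion; sequences are dummies
records_from_counts <- function(species, counts, seq_len = 12L) {
  rep_sp <- rep(species, counts)
  data.frame(record_id = sprintf("rec%05d", seq_along(rep_sp)),
             species = rep_sp,
             sequence = strrep("ACGT", ceiling(seq_len / 4)),
             stringsAsFactors = FALSE)
}

random_dna <- function(n, len_range = c(50L, 300L)) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"),
                 sample(len_range[1]:len_range[2], 1L), replace = TRUE),
          collapse = "")
  }, character(1))
}

# small separable dataset for classifier tests
easy_sim <- function(n_species = 4L, counts = 10L, seed = 11L,
                     within_noise = 0.005) {
  generate_dataset(synthetic_config(
    n_species = n_species, counts = counts,
    length_range = c(150L, 300L), between_divergence = 0.1,
    within_noise = within_noise, seed = seed))
}
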