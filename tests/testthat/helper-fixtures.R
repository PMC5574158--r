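# Shared fixtures.  Everything is generated in code under fixed seeds.

# a small calibrated panel + QTN set used by several files
calibrated_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      p <- draw_site_frequencies(2000, 0.2, seed = 101)
      panel <- make_founder_panel(p, 205, seed = 102)
      eff <- sample_qtn_effects(seed = 103)
      qtn <- assign_qtn_sites(eff, panel_freqs(panel), seed = 104)
      cache <<- list(panel = panel, qtn = qtn)
    }
    cache
  }
})

# hand-built QTN set: `n_pairs` pairs over the first 2*n_pairs sites,
# dominant allele 1 everywhere, given pair values
manual_qtn <- function(z_pairs, dominant = 1L) {
  n <- 2L * length(z_pairs)
  structure(
    data.frame(site_id = seq_len(n),
               effect = rep(z_pairs, each = 2L),
               abs_effect = rep(abs(z_pairs), each = 2L),
               source = "exponential",
               dominant_allele = rep(dominant, n),
               increasing_allele = rep(ifelse(z_pairs > 0, dominant,
                                              1L - dominant), each = 2L),
               pair_id = rep(seq_along(z_pairs), each = 2L),
               z = rep(z_pairs, each = 2L),
               a = rep(z_pairs, each = 2L)),
    class = c("episel_qtn", "data.frame"))
}

# single-chromosome site table for meiosis tests
one_chrom_sites <- function(n_sites, length_cm = 100, length_bp = 1e6,
                            chrom = "2") {
  chromosomes <- data.frame(chrom = chrom, length_bp = length_bp,
                            length_cm = length_cm,
                            stringsAsFactors = FALSE)
  sites <- data.frame(site_id = seq_len(n_sites), chrom = chrom,
                      pos_bp = round(seq(1, length_bp,
                                         length.out = n_sites)),
                      ref_allele = "A", alt_allele = "T",
                      stringsAsFactors = FALSE)
  make_genetic_map(sites, chromosomes)
}

# population with one individual holding the given haplotype pair
single_parent_pop <- function(h1, h2, sex, sites) {
  H <- rbind(as.integer(h1), as.integer(h2))
  episel:::new_population(H, sex, generation = 0L, sites = sites)
}

# shared scaled-down experiment runs for the acceptance statistics;
# computed lazily once per test session
experiment_runs <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      run_cell <- function(arch, dir, seed, track = FALSE) {
        cfg <- experiment_config(
          arch, "A-SEQ", dir, n_generations = 7L, N = 500L,
          n_replicates = 1L, n_sites = 1500L, n_iter = 2000L,
          burn_in = 500L, seed = seed, keep_populations = TRUE,
          progeny_test_n = if (track) 60L else 0L,
          progeny_test_offspring = 400L)
        suppressMessages(run_experiment(cfg))
      }
      cache <<- list(
        add_up = lapply(c(301L, 302L, 303L),
                        function(s) run_cell("additive", "up", s)),
        add_down = lapply(c(311L, 312L, 313L),
                          function(s) run_cell("additive", "down", s,
                                               track = TRUE)),
        epi_up = lapply(c(321L, 322L, 323L),
                        function(s) run_cell("complementary", "up", s)))
    }
    cache
  }
})

terminal_response <- function(res)
  res$metrics$response_sd[res$metrics$generation == res$config$n_generations]
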