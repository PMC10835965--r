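# Shared synthetic fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(key, builder) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, builder(), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

tiny_genome <- function() toy_genome(c(chr1 = 40e6), gene_spacing = 50e3)

tiny_design <- function() {
  fixture("tiny_design", function() {
    build_design(c(TSS = 3, ENH = 3), guides_per_target = 4, n_nt = 8,
                 genome = tiny_genome(), seed = 42)
  })
}

# small screen with planted effects (strong means so effects are visible)
tiny_screen <- function() {
  fixture("tiny_screen", function() {
    simulate_screen(
      tiny_design(),
      sim_params(n_cells = 4000, n_genes = 400, seed = 99,
                 expected_gene_mean_range = c(1, 10)))
  })
}

# same design, no planted effects anywhere
tiny_null_screen <- function() {
  fixture("tiny_null_screen", function() {
    simulate_screen(
      tiny_design(),
      sim_params(n_cells = 4000, n_genes = 400, seed = 77,
                 knockdown_by_class = c(TSS = 0, ENH = 0,
                                        CCRE_INTRONIC = 0,
                                        CCRE_INTERGENIC = 0, LCR = 0)))
  })
}

tiny_analysis <- function() {
  fixture("tiny_analysis", function() {
    analyze_screen(tiny_screen(), nt_background_n = 600, seed = 1)
  })
}
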