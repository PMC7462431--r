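# The end-to-end synthetic study shared by the acceptance tests. Generated
# once per test run at the default cohort conditions; the FC grids per
# filter-graph variant are cached alongside because both the fit and the
# community analyses consume them.

acceptance_study <- function() {
  cached("acceptance_study", {
    study <- make_cohort(seed = 20)
    cons <- consensus_sc(study$subject_scs, study$parcellation)
    G_grid <- c(0, 0.02, 0.05, 0.1, 0.2, 0.5, 1, 5)
    graphs <- list(
      ed_match = build_filter_graph("ed_match", cons, study$parcellation),
      ed_full = build_filter_graph("ed_full", cons, study$parcellation))
    fcs <- lapply(graphs, function(g)
      study_fc_grid(study$epochs, g, G_grid, study$band))
    list(study = study, cons = cons, G_grid = G_grid, graphs = graphs,
         fcs = fcs)
  })
}
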