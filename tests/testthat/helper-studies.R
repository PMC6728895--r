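# Full-scale study runs shared by the table-reproduction tests. Each
# condition is computed once per session (3 replications at the study
# sample sizes) and cached.

.study_cache <- new.env(parent = emptyenv())

study_run <- function(name) {
  if (!is.null(.study_cache[[name]])) return(.study_cache[[name]])
  cfg <- switch(name,
    s1_high_d = run_config(design_preset("study1_high"), criterion = "D",
                           replications = 3, base_seed = 1100),
    s1_mod_d = run_config(design_preset("study1_moderate"), criterion = "D",
                          replications = 3, base_seed = 1200),
    s1_mod_corr_true = run_config(design_preset("study1_moderate",
                                                correlated = TRUE),
                                  replications = 3, base_seed = 1300,
                                  theta_source = "true"),
    s1_high_ba = run_config(design_preset("study1_high"),
                            criterion = "bayesA", replications = 3,
                            base_seed = 1400, pattern_step = FALSE),
    s2_high_d = run_config(design_preset("study2_high"), criterion = "D",
                           replications = 3, base_seed = 1500),
    s2_high_ba = run_config(design_preset("study2_high"),
                            criterion = "bayesA", replications = 3,
                            base_seed = 1600, pattern_step = FALSE),
    s1_high_ba_var = run_config(design_preset("study1_high"),
                                criterion = "bayesA",
                                stopping = stopping_variable(),
                                replications = 3, base_seed = 1700),
    s1_mod_ba_var = run_config(design_preset("study1_moderate"),
                               criterion = "bayesA",
                               stopping = stopping_variable(),
                               replications = 3, base_seed = 1800,
                               pattern_step = FALSE),
    stop("unknown study condition: ", name))
  .study_cache[[name]] <- run_study(cfg)
  .study_cache[[name]]
}
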