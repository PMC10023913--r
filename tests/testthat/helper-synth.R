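# Shared fixture builders. Everything is generated in code at test time;
# sizes are kept small except where a check is explicitly about the
# full eight-year design.

tiny_env <- function(n_days = 400, seed = 1, ...) {
  generate_environment(synth_config(n_days = n_days, ...), seed = seed)
}

# environment + visits under the default ground truth (SO2 lag-5 effect)
tiny_study <- function(n_days = 400, seed = 1, effects = NULL,
                       baseline = NULL, link = "identity", ...) {
  cfg <- synth_config(n_days = n_days, link = link, ...)
  if (is.null(effects)) effects <- cfg$true_effects
  if (is.null(baseline)) baseline <- cfg$baseline_rate
  env <- generate_environment(cfg, seed = seed)
  vis <- generate_visits(env, effects, baseline, link, seed = seed)
  list(env = env, vis = vis, cfg = cfg)
}

no_effects <- data.frame(variable = character(), lag = integer(),
                         effect = numeric())
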