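# The full-scale demonstration run shared by the acceptance checks: the
# default synthetic world (48 stations x 5 years) through the whole pipeline
# with the cheapest hyperparameters of the stated search grid.

default_pipeline <- function() cached("default_pipeline", run_pipeline(
  run_config(world = world_config(seed = 11),
             features = generating_features(),
             hyper = hyper_params(300, "sqrt", 10),
             learner = "both", holdout_frac = 0.10, k = 10, seed = 11)))
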