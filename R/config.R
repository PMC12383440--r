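# YAML experiment configuration: one file with sections mirroring the
# config objects (phantom, preprocess, model, policy, train), consumed by
# the command-line runner and usable directly.

#' Read an experiment configuration from YAML
#'
#' Recognized top-level sections: `phantom`, `preprocess`, `model`,
#' `policy`, `train`; each key overrides the corresponding constructor
#' default.
#'
#' @param path YAML file path.
#' @return list with elements `phantom` ([PhantomSpec-class]),
#'   `preprocess`, `model`, `policy` and `train` ([TrainConfig-class]).
#' @export
readExperimentConfig <- function(path) {
  y <- yaml::read_yaml(path)
  build <- function(ctor, args) do.call(ctor, args %||% list())
  phantom <- build(PhantomSpec, y$phantom)
  preprocess <- build(PreprocessConfig, y$preprocess)
  model <- build(ModelConfig, y$model)
  policy <- build(MissingPolicy, y$policy)
  trainArgs <- y$train %||% list()
  trainArgs$policy <- policy
  trainArgs$model <- model
  trainArgs$preprocess <- preprocess
  train <- do.call(TrainConfig, trainArgs)
  list(phantom = phantom, preprocess = preprocess, model = model,
       policy = policy, train = train)
}
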