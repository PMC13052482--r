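# JSON model serialization: trees as nested nodes (feature name, threshold,
# children; leaf vote at the tips), plus learner weights and metadata.
# Numbers are written at full precision so a round trip reproduces
# predictions exactly.

tree_to_nested <- function(tree, features, k = 1L) {
  if (tree$feature[k] < 0L) {
    return(list(vote = if (tree$vote[k] > 0) "malignant" else "benign"))
  }
  list(
    feature = features[tree$feature[k] + 1L],
    threshold = tree$threshold[k],
    gain = tree$gain[k],
    node_weight = tree$node_weight[k],
    left = tree_to_nested(tree, features, tree$left[k] + 1L),
    right = tree_to_nested(tree, features, tree$right[k] + 1L)
  )
}

nested_to_tree <- function(node, features) {
  feature <- integer(0); threshold <- numeric(0); left <- integer(0)
  right <- integer(0); vote <- integer(0); gain <- numeric(0)
  node_weight <- numeric(0)
  add <- function(node) {
    k <- length(feature) + 1L
    feature[k] <<- -1L; threshold[k] <<- NA_real_; left[k] <<- -1L
    right[k] <<- -1L; vote[k] <<- 0L; gain[k] <<- 0; node_weight[k] <<- 0
    if (!is.null(node$vote)) {
      vote[k] <<- if (identical(node$vote, "malignant")) 1L else -1L
    } else {
      feature[k] <<- match(node$feature, features) - 1L
      threshold[k] <<- node$threshold
      gain[k] <<- node$gain %||% 0
      node_weight[k] <<- node$node_weight %||% 0
      left[k] <<- add(node$left) - 1L
      right[k] <<- add(node$right) - 1L
    }
    k
  }
  add(node)
  list(feature = feature, threshold = threshold, left = left, right = right,
       vote = vote, gain = gain, node_weight = node_weight,
       n_branch = sum(feature >= 0L))
}

#' Serialize / restore an ensemble model as JSON
#'
#' Trees are stored as nested split nodes with feature names and leaf votes;
#' learner weights, training errors, hyperparameters and the seed round-trip
#' exactly (predictions from the restored model are identical).
#'
#' @param model An `ensemble_model`.
#' @param path Output / input JSON file.
#' @return `write_model_json` returns `path` invisibly; `read_model_json`
#'   returns the restored `ensemble_model`.
#' @export
write_model_json <- function(model, path) {
  obj <- list(
    format = "phasorboost_ensemble",
    classes = c(negative = "benign", positive = "malignant"),
    features = model$features,
    hyperparameters = unclass(model$hp),
    seed = model$seed,
    degenerate = model$degenerate,
    alphas = model$alphas,
    epsilons = model$epsilons,
    trees = lapply(model$trees, tree_to_nested, features = model$features)
  )
  # I(17) significant digits: doubles survive the decimal round trip exactly
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$format, "phasorboost_ensemble")) {
    abort("not a phasorboost model file.", class = "phb_input_error")
  }
  features <- unlist(obj$features)
  structure(
    list(
      trees = lapply(obj$trees, nested_to_tree, features = features),
      alphas = as.numeric(unlist(obj$alphas)),
      epsilons = as.numeric(unlist(obj$epsilons)),
      features = features,
      hp = hyperparameters(obj$hyperparameters$learning_rate,
                           obj$hyperparameters$n_learners,
                           obj$hyperparameters$max_nodes),
      seed = obj$seed,
      degenerate = isTRUE(obj$degenerate),
      history = NULL
    ),
    class = "ensemble_model"
  )
}
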