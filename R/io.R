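#' Write a dataset to disk
#'
#' Persists a dataset as a directory holding a plain-text manifest
#' (`manifest.csv`: neuron id, position, depth, session, mouse, genotype,
#' ground-truth type) plus a binary container with the trial matrices and
#' protocols. Regenerating a dataset from the same configuration and seed
#' reproduces the files exactly.
#'
#' @param dataset An `sc_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(dataset_manifest(dataset),
                   file.path(dir, "manifest.csv"), row.names = FALSE)
  saveRDS(dataset, file.path(dir, "dataset.rds"))
  invisible(dir)
}

#' Read a dataset written by [write_dataset()]
#' @param dir Dataset directory.
#' @return The `sc_dataset`.
#' @export
read_dataset <- function(dir) {
  readRDS(file.path(dir, "dataset.rds"))
}

#' Manifest data frame of a dataset
#'
#' @param dataset An `sc_dataset`.
#' @return Data frame with one row per neuron: `neuron_id`, `x_um`,
#'   `y_um`, `depth_um`, `session`, `mouse`, `genotype`, `true_type`.
#' @export
dataset_manifest <- function(dataset) {
  do.call(rbind, lapply(dataset$neurons, function(nr) {
    data.frame(neuron_id = nr$neuron_id,
               x_um = nr$position[1], y_um = nr$position[2],
               depth_um = nr$depth, session = nr$session_id,
               mouse = nr$mouse_id, genotype = nr$genotype,
               true_type = nr$true_type)
  }))
}
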