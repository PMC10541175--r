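#' Write a task dataset to a columnar on-disk container
#'
#' Serializes to a directory holding `inputs.csv` (columns `split`,
#' `pattern`, `x1..xD`), `targets.csv` (`split`, `pattern`, `y1..yQ`) and
#' `metadata.json`. Numeric values use shortest round-trip formatting, so a
#' write/read cycle is lossless.
#'
#' @param ds a [task_dataset()].
#' @param path directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_task_dataset <- function(ds, path) {
  validate_task_dataset(ds)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  tab <- function(train, test, prefix) {
    m <- rbind(train, test)
    # shortest-exact decimal representation so the round trip is lossless
    m17 <- apply(m, 2, function(col) sprintf("%.17g", col))
    colnames(m17) <- paste0(prefix, seq_len(ncol(m)))
    data.frame(split = rep(c("train", "test"), c(nrow(train), nrow(test))),
               pattern = c(seq_len(nrow(train)), seq_len(nrow(test))),
               m17, check.names = FALSE)
  }
  data.table::fwrite(tab(ds$train_inputs, ds$test_inputs, "x"),
                     file.path(path, "inputs.csv"))
  data.table::fwrite(tab(ds$train_targets, ds$test_targets, "y"),
                     file.path(path, "targets.csv"))
  meta <- c(list(task_kind = ds$task_kind, input_mode = ds$input_mode),
            ds$metadata)
  jsonlite::write_json(meta, file.path(path, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a task dataset written by [write_task_dataset()]
#'
#' @param path directory containing the container files.
#' @return a [task_dataset()].
#' @export
read_task_dataset <- function(path) {
  inputs <- data.table::fread(file.path(path, "inputs.csv"))
  targets <- data.table::fread(file.path(path, "targets.csv"))
  meta <- jsonlite::read_json(file.path(path, "metadata.json"),
                              simplifyVector = TRUE)
  part <- function(dt, split) {
    df <- as.data.frame(dt)
    cols <- setdiff(names(df), c("split", "pattern"))
    m <- vapply(df[df$split == split, cols, drop = FALSE], as.numeric,
                numeric(sum(df$split == split)))
    m <- matrix(m, ncol = length(cols))
    dimnames(m) <- NULL
    m
  }
  task_dataset(part(inputs, "train"), part(targets, "train"),
               part(inputs, "test"), part(targets, "test"),
               task_kind = meta$task_kind, input_mode = meta$input_mode,
               metadata = meta[setdiff(names(meta), c("task_kind", "input_mode"))])
}
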