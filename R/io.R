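# Cohort directory container: flat little-endian float64 arrays with JSON
# sidecars, a JSON manifest carrying shapes and the config hash, and a
# YAML echo of the configuration. Round trips are bit-exact.

COHORT_CONTAINER_VERSION <- "betavigor-cohort-1"

write_array_bin <- function(x, stem, meta) {
  writeBin(as.vector(x), paste0(stem, ".bin"), size = 8, endian = "little")
  meta$shape <- dim(x)
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  list(file = basename(paste0(stem, ".bin")), shape = dim(x))
}

read_array_bin <- function(stem) {
  sidecar <- paste0(stem, ".json")
  if (!file.exists(sidecar))
    stop("read_cohort: missing sidecar ", basename(sidecar))
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  shape <- as.integer(meta$shape)
  binfile <- paste0(stem, ".bin")
  n_stored <- file.info(binfile)$size / 8
  if (!isTRUE(n_stored == prod(shape)))
    stop("read_cohort: shape mismatch for ", basename(binfile),
         ": sidecar declares ", paste(shape, collapse = "x"),
         " (", prod(shape), " values) but file holds ", n_stored)
  x <- readBin(binfile, what = "double", n = prod(shape), size = 8,
               endian = "little")
  dim(x) <- shape
  list(data = x, meta = meta)
}

#' Write a cohort to a directory
#'
#' Per subject: epochs, parcel time courses and kinematics as flat
#' float64 + JSON sidecar pairs; plus `manifest.json` (file list, shapes,
#' config hash) and a `config.yaml` echo.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir target directory (created if needed).
#' @return the manifest, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- list()
  for (s in seq_along(cohort$subjects)) {
    sub <- cohort$subjects[[s]]
    id <- cohort$truth$subjects$subject[s]
    if (!is.null(sub$epochs)) {
      e <- sub$epochs
      files[[length(files) + 1L]] <- write_array_bin(
        e$data, file.path(dir, paste0(id, "_epochs")),
        list(kind = "epochs", fs = e$fs, t0 = e$t0, labels = e$labels,
             channel_ids = e$channel_ids, positions = e$positions,
             subject_id = e$subject_id))
    }
    p <- sub$parcels
    files[[length(files) + 1L]] <- write_array_bin(
      p$data, file.path(dir, paste0(id, "_parcels_", p$band$name)),
      list(kind = "parcels", fs = p$fs, t0 = p$t0,
           parcel_names = p$parcel_names, seed_name = p$seed_name,
           band = unclass(p$band), labels = p$labels))
    k <- sub$kinematics
    lens <- vapply(k$lux, length, 0L)
    files[[length(files) + 1L]] <- write_array_bin(
      matrix(c(unlist(k$lux), unlist(k$acc))),
      file.path(dir, paste0(id, "_kinematics")),
      list(kind = "kinematics", fs_behav = k$fs_behav, lengths = lens,
           go_cue_index = k$go_cue_index, labels = k$labels))
  }
  jsonlite::write_json(cohort$truth,
                       file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  manifest <- list(
    container_version = COHORT_CONTAINER_VERSION,
    n_subjects = length(cohort$subjects),
    subjects = cohort$truth$subjects$subject,
    config_hash = config_hash(unclass(cohort$config)),
    files = files
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cfg <- unclass(cohort$config)
  cfg$band <- unclass(cfg$band)
  cfg$rt_ms <- lapply(cfg$rt_ms, as.list)
  cfg$mt_ms <- lapply(cfg$mt_ms, as.list)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(manifest)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir cohort directory.
#' @return a `cohort` object; arrays are bit-identical to what was written.
#' @export
read_cohort <- function(dir) {
  manifest_file <- file.path(dir, "manifest.json")
  if (!file.exists(manifest_file))
    stop("read_cohort: no manifest.json in ", dir)
  manifest <- jsonlite::read_json(manifest_file, simplifyVector = TRUE)
  if (!identical(manifest$container_version, COHORT_CONTAINER_VERSION))
    stop("read_cohort: unknown container version '",
         manifest$container_version, "'")
  cfg_list <- yaml::read_yaml(file.path(dir, "config.yaml"))
  cfg_list$band <- do.call(band_def, cfg_list$band)
  cfg_list$rt_ms <- lapply(cfg_list$rt_ms, unlist)
  cfg_list$mt_ms <- lapply(cfg_list$mt_ms, unlist)
  config <- do.call(sim_config, cfg_list[setdiff(names(cfg_list), character())])
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  truth$subjects <- as.data.frame(truth$subjects,
                                  stringsAsFactors = FALSE)
  truth$trials <- as.data.frame(truth$trials, stringsAsFactors = FALSE)
  subjects <- lapply(manifest$subjects, function(id) {
    out <- list(epochs = NULL, parcels = NULL, kinematics = NULL,
                trials = NULL)
    estem <- file.path(dir, paste0(id, "_epochs"))
    if (file.exists(paste0(estem, ".bin"))) {
      r <- read_array_bin(estem)
      out$epochs <- epoch_set(r$data, r$meta$fs, r$meta$t0, r$meta$labels,
                              r$meta$channel_ids,
                              matrix(unlist(r$meta$positions), ncol = 2),
                              r$meta$subject_id)
    }
    pfiles <- list.files(dir, pattern = paste0("^", id, "_parcels_.*\\.bin$"))
    if (length(pfiles) != 1L)
      stop("read_cohort: expected one parcel file for ", id)
    r <- read_array_bin(file.path(dir, sub("\\.bin$", "", pfiles)))
    out$parcels <- parcel_tc(r$data, r$meta$fs, r$meta$t0,
                             r$meta$parcel_names, r$meta$seed_name,
                             do.call(band_def, r$meta$band), r$meta$labels)
    r <- read_array_bin(file.path(dir, paste0(id, "_kinematics")))
    lens <- as.integer(r$meta$lengths)
    flat <- as.vector(r$data)
    half <- sum(lens)
    splitv <- function(v) split(v, rep(seq_along(lens), lens))
    lux <- unname(splitv(flat[seq_len(half)]))
    acc <- unname(splitv(flat[half + seq_len(half)]))
    out$kinematics <- kinematic_traces(lux, acc, r$meta$fs_behav,
                                       as.integer(r$meta$go_cue_index),
                                       r$meta$labels)
    out
  })
  trials <- truth$trials
  for (s in seq_along(subjects))
    subjects[[s]]$trials <- trials[trials$subject ==
                                     manifest$subjects[s], , drop = FALSE]
  structure(list(subjects = subjects,
                 truth = list(subjects = truth$subjects, trials = trials),
                 config = config),
            class = "cohort")
}
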