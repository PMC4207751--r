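# Formats, configuration and the end-to-end pipeline.
#
# Conventions: FASTA in/out via Biostrings; TSV reports carry '#' header
# lines and use 0-based, half-open coordinates on disk (in-memory tibbles
# follow R's 1-based convention); logging goes to standard error via
# message(); results go to files only.

#' Read a protein FASTA file
#'
#' @param path Existing FASTA file with at least one record.  Duplicate
#'   ids (first whitespace-delimited header token) and empty records are
#'   errors naming the offender.  Sequences are uppercased and a terminal
#'   `*` stop is stripped; CRLF input is handled transparently.
#' @return Tibble with `id`, `description` and `sequence`, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("FASTA file not found: ", path))
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) abort(paste0("cannot parse FASTA ", path, ": ",
                                     conditionMessage(e)))
  )
  if (length(set) == 0) abort(paste0("no FASTA records in ", path))
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers),
                 sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate FASTA id(s) in ", path, ": ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  seqs <- toupper(as.character(set))
  seqs <- sub("\\*$", "", seqs)
  empty <- ids[!nzchar(seqs)]
  if (length(empty)) {
    abort(paste0("empty FASTA record(s) in ", path, ": ",
                 paste(empty, collapse = ", ")))
  }
  tibble(id = ids, description = unname(desc), sequence = unname(seqs))
}

#' Write sequences to FASTA
#'
#' @param x Named character vector, or a data frame with `id` and
#'   `sequence` (and optionally `description`) columns.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  if (is.character(x)) {
    x <- tibble(id = names(x) %||% as.character(seq_along(x)),
                sequence = unname(x))
  }
  headers <- if ("description" %in% names(x) && any(nzchar(x$description))) {
    ifelse(nzchar(x$description), paste(x$id, x$description), x$id)
  } else {
    x$id
  }
  set <- Biostrings::BStringSet(setNames(x$sequence, headers))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

tsv_header <- function(what, coords = TRUE) {
  c(paste0("# acylscan ", what),
    if (coords) "# coordinates: 0-based, half-open [start, end)")
}

offset_to_disk <- function(df) {
  # converts 1-based inclusive offset columns to 0-based starts
  for (nm in grep("^offset_", names(df), value = TRUE)) {
    df[[nm]] <- df[[nm]] - 1L
  }
  df
}

write_report_tsv <- function(df, path, what, coords = TRUE) {
  con <- file(path, open = "wb")  # binary: byte-identical across platforms
  on.exit(close(con))
  writeLines(tsv_header(what, coords), con)
  df <- as.data.frame(df)
  df <- df[, !map_lgl(df, is.list), drop = FALSE]
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Write a classification report
#'
#' Tab-separated, commented header, 0-based half-open motif coordinates.
#'
#' @param res An `acyl_classification`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_classification_tsv <- function(res, path) {
  write_report_tsv(offset_to_disk(res), path, "classification report")
}

#' Write a presence/absence matrix
#'
#' @param pres An `acyl_presence`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_presence_tsv <- function(pres, path) {
  df <- as.data.frame(pres)
  for (nm in names(df)[-1]) df[[nm]] <- as.integer(df[[nm]])
  write_report_tsv(df, path, "presence/absence matrix (1 = present)",
                   coords = FALSE)
}

default_config <- function() {
  list(
    mode = "synthetic",
    scenario = "opisthokont8",
    divergence = 0.05,
    proteome_size = 300,
    seed = 17,
    profiles = NULL,
    e_cutoff = 0.05,
    min_margin = 2,
    min_motifs = 4,
    dbm_mode = "soft",
    gap_open = 11,
    gap_extend = 1,
    lambda = 0.267,
    K = 0.041,
    alpha = 0.5,
    pssm_min = 0,
    proteome_dir = NULL,
    seeds_fasta = NULL,
    reference_fasta = NULL,
    out_dir = "acylscan_run"
  )
}

#' Read a pipeline run configuration
#'
#' YAML with the keys of the default configuration (unknown keys are an
#' error, not silently ignored); omitted keys take their defaults.  The
#' configuration round-trips losslessly through [write_run_config()].
#'
#' @param path YAML file.
#' @return Named list of class `acyl_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  user <- yaml::read_yaml(path) %||% list()
  defaults <- default_config()
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  cfg <- modifyList(defaults, user)
  num_keys <- c("divergence", "proteome_size", "seed", "e_cutoff",
                "min_margin", "min_motifs", "gap_open", "gap_extend",
                "lambda", "K", "alpha", "pssm_min")
  for (k in num_keys) {
    if (!is.numeric(cfg[[k]]) || !is.finite(cfg[[k]])) {
      abort(paste0("config key '", k, "' must be a finite number"))
    }
  }
  structure(cfg, class = "acyl_config")
}

#' Write a pipeline run configuration
#' @param cfg An `acyl_config` (or plain named list of known keys).
#' @param path Output YAML file.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg)[!map_lgl(unclass(cfg), is.null)], path)
  invisible(path)
}

#' Run the full pipeline
#'
#' Composes the stages end to end -- survey, classification of validated
#' hits, PTS1 calls, presence/absence matrix, neighbour-joining tree per
#' family -- and writes a report bundle: `survey_log.tsv`,
#' `classification.tsv`, `presence_absence.tsv`, `trees/<family>.nwk` and a
#' machine-readable `manifest.json` (configuration, seeds, package version,
#' output checksums).  Deterministic given the configuration: rerunning
#' with the same manifest reproduces the bundle byte for byte.
#'
#' In `mode: synthetic` the inputs are generated in-package from the
#' configured scenario and seed; in `mode: files` they are read from
#' `proteome_dir` (one FASTA per proteome), `seeds_fasta` (seed records
#' named `<family>|<id>`) and `reference_fasta`.
#'
#' @param config An `acyl_config`, or the path of a YAML configuration.
#' @param out_dir Output directory (default from the configuration).
#' @return List of class `acyl_run`: the survey, classification, presence
#'   matrix, tree paths and the manifest path.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  cfg <- config
  out_dir <- out_dir %||% cfg$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "trees"), showWarnings = FALSE)
  profiles <- acyl_profiles(cfg$profiles)

  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
  }

  inputs <- stage("inputs", {
    if (cfg$mode == "synthetic") {
      generate_survey_set(plan = survey_plan(cfg$scenario),
                          divergence = cfg$divergence,
                          proteome_size = cfg$proteome_size,
                          profiles = profiles, seed = cfg$seed)
    } else if (cfg$mode == "files") {
      if (is.null(cfg$proteome_dir) || is.null(cfg$seeds_fasta) ||
          is.null(cfg$reference_fasta)) {
        abort("mode 'files' needs proteome_dir, seeds_fasta and reference_fasta")
      }
      files <- sort(list.files(cfg$proteome_dir, pattern = "\\.(fa|fasta|faa)$",
                               full.names = TRUE))
      if (length(files) == 0) abort("no FASTA files in proteome_dir")
      proteomes <- map(files, function(f) {
        recs <- read_fasta(f)
        setNames(recs$sequence, recs$id)
      })
      names(proteomes) <- tools::file_path_sans_ext(basename(files))
      ref <- read_fasta(cfg$reference_fasta)
      seeds_recs <- read_fasta(cfg$seeds_fasta)
      fam <- sub("\\|.*$", "", seeds_recs$id)
      sid <- sub("^[^|]*\\|", "", seeds_recs$id)
      if (any(fam == seeds_recs$id)) {
        abort("seed ids must be of the form <family>|<reference id>")
      }
      list(proteomes = proteomes,
           reference = setNames(ref$sequence, ref$id),
           seeds = split(sid, fam), truth = NULL)
    } else {
      abort(paste0("unknown mode '", cfg$mode, "'"))
    }
  })

  survey <- stage("survey", {
    iterative_survey(inputs$proteomes, inputs$seeds, inputs$reference,
                     profiles = profiles, e_cutoff = cfg$e_cutoff,
                     pssm_min = cfg$pssm_min, alpha = cfg$alpha,
                     dbm_mode = cfg$dbm_mode, gap_open = cfg$gap_open,
                     gap_extend = cfg$gap_extend, lambda = cfg$lambda,
                     K = cfg$K)
  })

  hits <- survey$validated
  classification <- stage("classify", {
    if (nrow(hits) == 0) {
      classify_sequences(tibble(id = character(), sequence = character()),
                         profiles)
    } else {
      seqs <- map_chr(seq_len(nrow(hits)), function(i) {
        inputs$proteomes[[hits$proteome[i]]][[hits$id[i]]]
      })
      classify_sequences(
        tibble(id = paste0(hits$proteome, "::", hits$id),
               proteome = hits$proteome, sequence = seqs),
        profiles, min_margin = cfg$min_margin, min_motifs = cfg$min_motifs,
        dbm_mode = cfg$dbm_mode
      )
    }
  })

  trees <- stage("trees", {
    out <- list()
    for (f in unique(hits$family)) {
      sub <- hits[hits$family == f, ]
      if (nrow(sub) < 3) next
      seqs <- setNames(
        map_chr(seq_len(nrow(sub)), function(i) {
          inputs$proteomes[[sub$proteome[i]]][[sub$id[i]]]
        }),
        paste0(sub$proteome, "::", sub$id)
      )
      tr <- neighbor_joining(pairwise_distances(seqs))
      p <- file.path(out_dir, "trees", paste0(gsub("-", "_", f), ".nwk"))
      ape::write.tree(tr, p)
      out[[f]] <- p
    }
    out
  })

  message("survey validated ", nrow(hits), " hit(s) across ",
          length(inputs$proteomes), " proteome(s)")

  log_path <- file.path(out_dir, "survey_log.tsv")
  write_report_tsv(survey$log, log_path, "survey additions log",
                   coords = FALSE)
  cls_path <- file.path(out_dir, "classification.tsv")
  write_classification_tsv(classification, cls_path)
  pres_path <- file.path(out_dir, "presence_absence.tsv")
  write_presence_tsv(survey$presence, pres_path)

  cfg_path <- file.path(out_dir, "config.yaml")
  write_run_config(cfg, cfg_path)
  outputs <- c(log_path, cls_path, pres_path, unlist(trees))
  manifest <- list(
    package = "acylscan",
    version = as.character(utils::packageVersion("acylscan")),
    config = unclass(cfg)[!map_lgl(unclass(cfg), is.null)],
    config_md5 = unname(tools::md5sum(cfg_path)),
    outputs = as.list(setNames(unname(tools::md5sum(outputs)),
                               basename(outputs)))
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  structure(
    list(survey = survey, classification = classification,
         presence = survey$presence, truth = inputs$truth,
         trees = trees, out_dir = out_dir, manifest = manifest_path),
    class = "acyl_run"
  )
}

#' @export
print.acyl_run <- function(x, ...) {
  cat("<acyl_run> ", x$out_dir, "\n", sep = "")
  print(x$survey)
  invisible(x)
}
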