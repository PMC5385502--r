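#' Read a FASTA file of protein sequences
#'
#' Wrapped and unwrapped records and CRLF line endings are accepted
#' (parsing via \pkg{Biostrings}).
#'
#' @param path FASTA file.
#' @param annotations optional data.frame (`id`, `phylum`,
#'   `class_annotation`) merged into the records; ids absent from it keep
#'   `"unknown"` labels.
#' @param numbering_offset residue label of the first residue (recycled).
#' @return Named list of [mature_sequence()] objects.
#' @export
read_fasta <- function(path, annotations = NULL, numbering_offset = 1L) {
  set <- tryCatch(Biostrings::readAAStringSet(path),
                  error = function(e) stop("cannot parse FASTA ", path, ": ",
                                           conditionMessage(e)))
  ids <- sub("\\s.*$", "", names(set))
  offs <- rep_len(as.integer(numbering_offset), length(set))
  out <- lapply(seq_along(set), function(i) {
    ph <- "unknown"; cl <- "unknown"
    if (!is.null(annotations)) {
      j <- match(ids[i], annotations$id)
      if (!is.na(j)) {
        ph <- as.character(annotations$phylum[j])
        cl <- as.character(annotations$class_annotation[j])
      }
    }
    mature_sequence(ids[i], as.character(set[[i]]), offs[i],
                    phylum = ph, class_annotation = cl)
  })
  names(out) <- ids
  out
}

#' Write sequences (or MSA rows) to FASTA
#'
#' @param seqs named character vector, list of [mature_sequence()], or `msa`.
#' @param path output file.
#' @param width line wrap width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  if (inherits(seqs, "msa")) {
    v <- seqs$rows; names(v) <- seqs$ids
  } else if (is.list(seqs)) {
    v <- vapply(seqs, seq_string, character(1L))
    names(v) <- vapply(seqs, function(s)
      if (inherits(s, "mature_sequence")) s$id else "", character(1L))
  } else v <- seqs
  set <- Biostrings::BStringSet(v)
  Biostrings::writeXStringSet(set, path, width = as.integer(width))
  invisible(path)
}

#' Read a FASTA-format multiple alignment
#' @param path aligned FASTA (rows may contain `-`).
#' @return An `msa` object.
#' @export
read_fasta_msa <- function(path) {
  set <- Biostrings::readBStringSet(path)
  rows <- toupper(as.character(set))
  if (length(unique(nchar(rows))) != 1L)
    stop("alignment rows differ in length in ", path)
  new_msa(sub("\\s.*$", "", names(set)), unname(rows))
}

#' Read a Clustal-format multiple alignment
#'
#' Accepts standard CLUSTAL W / Clustal Omega output: a `CLUSTAL` header,
#' blocks of `name sequence [cumulative count]` lines, optional conservation
#' lines, blank lines between blocks.
#'
#' @param path Clustal file (e.g. `.aln`).
#' @return An `msa` object.
#' @export
read_clustal <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || !grepl("^CLUSTAL", lines[1L]))
    stop("cannot parse Clustal ", path, ": missing CLUSTAL header")
  body <- lines[-1L]
  body <- body[nzchar(trimws(body)) & !grepl("^\\s", body)]
  ids <- character(0); rows <- list()
  for (ln in body) {
    parts <- strsplit(trimws(ln), "\\s+")[[1L]]
    if (length(parts) < 2L)
      stop("cannot parse Clustal ", path, ": malformed line: ", ln)
    id <- parts[1L]
    chunk <- paste(grep("^[0-9]+$", parts[-1L], value = TRUE,
                        invert = TRUE), collapse = "")
    if (!id %in% ids) { ids <- c(ids, id); rows[[id]] <- "" }
    rows[[id]] <- paste0(rows[[id]], chunk)
  }
  new_msa(ids, toupper(unlist(rows[ids], use.names = FALSE)))
}

#' Read / write tab-separated tables with header rows
#' @param path file path.
#' @return `read_tsv`: a data.frame.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname read_tsv
#' @param x data.frame to write.
#' @return `write_tsv`: `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

pipeline_defaults <- function() list(
  fasta = NULL, msa = NULL, annotations = NULL, out_dir = NULL,
  mode = "strict", matrix = "BLOSUM62", gap_open = 10, gap_extend = 0.5,
  components = 2L, nx = 7L, ny = 2L, consensus_threshold = 0.5,
  purity = 0.8, min_cell = 3L, seed = 1L)

#' Validate a pipeline configuration
#'
#' Fills defaults and rejects unknown keys before any stage runs.
#'
#' @param config named list of overrides (see [run_pipeline()]).
#' @return Complete validated configuration list.
#' @export
pipeline_config <- function(config = list()) {
  defs <- pipeline_defaults()
  unknown <- setdiff(names(config), names(defs))
  if (length(unknown) > 0L)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defs, config)
  if (is.null(cfg$fasta) && is.null(cfg$msa))
    stop("config needs 'fasta' (sequences) or 'msa' (pre-computed alignment)")
  if (is.null(cfg$out_dir)) stop("config needs 'out_dir'")
  if (cfg$nx < 1L || cfg$ny < 1L) stop("nx and ny must be >= 1")
  if (cfg$components < 2L) stop("components must be >= 2")
  cfg
}

#' Run the sequence-space pipeline end to end
#'
#' Scan for the canonical cysteine pattern, align (or import an alignment),
#' build the alignment similarity matrix, project onto principal
#' components, partition the PC1/PC2 plane, and write per-region consensus
#' sequences and summaries. All outputs are TSV/FASTA under `out_dir`, plus
#' a `manifest.json` recording inputs, parameters and seed; identical
#' config and inputs give identical outputs.
#'
#' @param config named list, validated by [pipeline_config()]: `fasta`
#'   (path, or a list of [mature_sequence()]), optional `msa` (path to an
#'   aligned FASTA, skips the built-in aligner), optional `annotations`
#'   (path to TSV id/phylum/class_annotation), `out_dir`, and stage
#'   parameters `mode`, `matrix`, `gap_open`, `gap_extend`, `components`,
#'   `nx`, `ny`, `consensus_threshold`, `purity`, `min_cell`, `seed`.
#' @return Invisibly, a list with the in-memory stage results: `scan`,
#'   `msa`, `projection`, `grid`, `summaries`, `consensus`, `manifest`.
#' @export
run_pipeline <- function(config) {
  cfg <- pipeline_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  ann <- NULL
  if (!is.null(cfg$annotations))
    ann <- if (is.character(cfg$annotations)) read_tsv(cfg$annotations)
           else cfg$annotations

  seqs <- NULL
  if (!is.null(cfg$fasta))
    seqs <- if (is.character(cfg$fasta)) read_fasta(cfg$fasta, ann)
            else cfg$fasta

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  scan_tab <- NULL
  if (!is.null(seqs)) {
    scan_tab <- stage("scan", scan_batch(seqs, mode = cfg$mode))
    write_tsv(scan_tab, file.path(cfg$out_dir, "scan.tsv"))
  }

  msa <- stage("msa", {
    if (!is.null(cfg$msa)) {
      if (is.character(cfg$msa)) read_fasta_msa(cfg$msa) else cfg$msa
    } else {
      keep <- seqs[vapply(seqs, function(s)
        scan_canonical(s, cfg$mode)$canonical, logical(1L))]
      if (length(keep) < 2L) stop("fewer than 2 canonical sequences")
      progressive_msa(keep, cfg$matrix, cfg$gap_open, cfg$gap_extend)
    }
  })
  write_fasta(msa, file.path(cfg$out_dir, "alignment.fasta"))

  proj <- stage("pca", {
    S <- pairwise_score_matrix(msa, cfg$matrix)
    eigen_project(S, cfg$components)
  })
  coords <- data.frame(id = rownames(proj$coordinates), proj$coordinates,
                       stringsAsFactors = FALSE)
  write_tsv(coords, file.path(cfg$out_dir, "coordinates.tsv"))
  write_tsv(data.frame(component = seq_along(proj$eigenvalues),
                       eigenvalue = proj$eigenvalues),
            file.path(cfg$out_dir, "eigenvalues.tsv"))

  grid <- stage("subdivide", partition(proj, cfg$nx, cfg$ny))
  ann_df <- if (!is.null(ann)) ann else if (!is.null(seqs)) data.frame(
    id = vapply(seqs, `[[`, character(1L), "id"),
    phylum = vapply(seqs, `[[`, character(1L), "phylum"),
    class_annotation = vapply(seqs, `[[`, character(1L), "class_annotation"),
    stringsAsFactors = FALSE) else
    data.frame(id = character(0), phylum = character(0),
               class_annotation = character(0))

  occupied <- sort(unique(grid$membership))
  summaries <- lapply(occupied, function(cell)
    summarize_region(grid, cell, ann_df, cfg$purity, cfg$min_cell))
  summ_tab <- do.call(rbind, lapply(summaries, function(s) data.frame(
    cell = s$cell, n = s$n_sequences, label = s$label,
    frac_ascomycota = s$phylum_fractions[["Ascomycota"]],
    frac_basidiomycota = s$phylum_fractions[["Basidiomycota"]],
    frac_class_I = s$class_fractions[["I"]],
    frac_class_II = s$class_fractions[["II"]],
    stringsAsFactors = FALSE)))
  write_tsv(summ_tab, file.path(cfg$out_dir, "regions.tsv"))

  consensus <- stage("consensus", {
    cs <- lapply(occupied, function(cell) {
      ids <- names(grid$membership)[grid$membership == cell]
      region_consensus(msa, ids, cfg$consensus_threshold)
    })
    names(cs) <- paste0("cell_", occupied)
    cs
  })
  non_sparse <- vapply(summaries, function(s) s$label != "sparse", logical(1L))
  if (any(non_sparse)) {
    v <- vapply(consensus[non_sparse], `[[`, character(1L), "letters")
    write_fasta(v, file.path(cfg$out_dir, "consensus.fasta"))
  }

  manifest <- list(
    package = "hydrin",
    version = as.character(utils::packageVersion("hydrin")),
    parameters = cfg[setdiff(names(cfg), c("fasta", "msa", "annotations"))],
    inputs = list(
      fasta = if (is.character(cfg$fasta)) cfg$fasta else "<in-memory>",
      msa = if (is.character(cfg$msa)) cfg$msa
            else if (is.null(cfg$msa)) "<built-in progressive aligner>"
            else "<in-memory>",
      n_sequences = length(msa$ids)),
    stages = c(if (!is.null(scan_tab)) "scan", "msa", "pca", "subdivide",
               "consensus"))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(scan = scan_tab, msa = msa, projection = proj, grid = grid,
                 summaries = summaries, consensus = consensus,
                 manifest = manifest))
}
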