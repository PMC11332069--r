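#' Read an aligned LC-MS feature table
#'
#' Parses a tab-separated alignment export (one row per feature: id, m/z,
#' retention time, then one intensity column per sample) together with a
#' sample sheet describing each sample's role. Column headers are matched
#' against a configurable alias list so that both a generic
#' `feature_id / mz / rt` dialect and MS-DIAL-style headers
#' (`Alignment ID`, `Average Mz`, `Average Rt(min)`) parse without edits.
#'
#' Unparseable intensity cells and zeros become `NA` (an unintegrated peak is
#' unmeasured, not abundance zero).
#'
#' @param path tab-separated feature table.
#' @param sample_sheet CSV with columns `sample`, `group`, `is_qc`,
#'   `datan_chirality` (see [read_sample_sheet()]).
#' @param aliases named list of header aliases for the `feature_id`, `mz`
#'   and `rt` columns (case-insensitive).
#' @return A validated [feature_table()].
#' @export
read_feature_table <- function(path, sample_sheet,
                               aliases = feature_table_aliases()) {
  samples <- if (is.data.frame(sample_sheet)) sample_sheet
             else read_sample_sheet(sample_sheet)
  raw <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  hdr <- names(raw)
  find_col <- function(key) {
    hit <- which(tolower(hdr) %in% tolower(aliases[[key]]))
    if (!length(hit))
      stop("feature table format error: no column for '", key,
           "' (accepted: ", paste(aliases[[key]], collapse = ", "), ")",
           call. = FALSE)
    hit[1L]
  }
  id_c <- find_col("feature_id"); mz_c <- find_col("mz"); rt_c <- find_col("rt")
  missing_samples <- setdiff(samples$sample, hdr)
  if (length(missing_samples))
    stop("feature table format error: sample column(s) absent: ",
         paste(missing_samples, collapse = ", "), call. = FALSE)
  features <- data.frame(
    feature_id = as.character(raw[[id_c]]),
    mz = suppressWarnings(as.numeric(raw[[mz_c]])),
    rt = suppressWarnings(as.numeric(raw[[rt_c]])),
    stringsAsFactors = FALSE
  )
  intensity <- vapply(samples$sample, function(s)
    suppressWarnings(as.numeric(raw[[s]])), numeric(nrow(raw)))
  intensity <- matrix(intensity, nrow = nrow(raw),
                      dimnames = list(features$feature_id, samples$sample))
  intensity[!is.na(intensity) & intensity == 0] <- NA_real_
  ft <- feature_table(features, intensity, samples)
  message(sprintf("read_feature_table: %d features, %d samples from %s",
                  nrow(features), nrow(samples), path))
  ft
}

#' Default header aliases for feature-table parsing
#' @return Named list of accepted (case-insensitive) header names.
#' @export
feature_table_aliases <- function() {
  list(feature_id = c("feature_id", "id", "alignment id", "alignment_id"),
       mz = c("mz", "m/z", "average mz", "average_mz"),
       rt = c("rt", "rt(min)", "average rt(min)", "average_rt_min"))
}

#' Read a sample sheet
#'
#' CSV with one row per sample: `sample` (must match a feature-table column),
#' `group` (`positive`/`negative`, empty for QC pools), `is_qc`
#' (TRUE/FALSE), `datan_chirality` (`plus`/`minus` for QC pools, `none`
#' otherwise).
#'
#' @param path CSV file.
#' @return data.frame with normalized types.
#' @export
read_sample_sheet <- function(path) {
  s <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample", "group", "is_qc", "datan_chirality")
  if (!all(need %in% names(s)))
    stop("sample sheet format error: missing column(s): ",
         paste(setdiff(need, names(s)), collapse = ", "), call. = FALSE)
  s$sample <- as.character(s$sample)
  s$group <- ifelse(is.na(s$group) | s$group == "", NA_character_, s$group)
  s$is_qc <- as.logical(s$is_qc)
  s$datan_chirality <- ifelse(is.na(s$datan_chirality) | s$datan_chirality == "",
                              "none", s$datan_chirality)
  s
}

#' Write a feature table and its sample sheet
#'
#' Inverse of [read_feature_table()]; `NA` intensities are written as empty
#' cells. Numeric columns carry full double precision (15 significant
#' digits).
#'
#' @param ft a [feature_table()].
#' @param path output TSV path for the feature table.
#' @param sample_path output CSV path for the sample sheet.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(ft, path, sample_path) {
  validate_feature_table(ft)
  out <- data.frame(feature_id = ft$features$feature_id,
                    mz = format(ft$features$mz, digits = 15, trim = TRUE),
                    rt = format(ft$features$rt, digits = 15, trim = TRUE),
                    stringsAsFactors = FALSE, check.names = FALSE)
  ints <- apply(ft$intensity, 2, function(v)
    ifelse(is.na(v), "", format(v, digits = 15, trim = TRUE)))
  out <- cbind(out, as.data.frame(ints, check.names = FALSE,
                                  stringsAsFactors = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  ss <- ft$samples
  ss$group[is.na(ss$group)] <- ""
  utils::write.csv(ss, sample_path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a metabolite standards library
#'
#' CSV with columns `compound`, `enantiomer` (`D`, `L`, `E1`, `E2`, or
#' `achiral`), `expected_mz` (Th) and `expected_rt` (minutes). D/L calls for
#' annotated chiral compounds come from these per-enantiomer expected RTs;
#' no global elution-order rule is assumed.
#'
#' @param path CSV file.
#' @return data.frame of class `StandardsLibrary`.
#' @export
read_standards <- function(path) {
  lib <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("compound", "enantiomer", "expected_mz", "expected_rt")
  if (!all(need %in% names(lib)))
    stop("standards library format error: missing column(s): ",
         paste(setdiff(need, names(lib)), collapse = ", "), call. = FALSE)
  validate_standards(lib)
}

validate_standards <- function(lib) {
  ok_labels <- c("D", "L", "E1", "E2", "achiral")
  bad <- which(!lib$enantiomer %in% ok_labels)
  if (length(bad))
    stop("standards library: invalid enantiomer label '",
         lib$enantiomer[bad[1L]], "' for compound '", lib$compound[bad[1L]],
         "'", call. = FALSE)
  if (any(!is.finite(lib$expected_mz) | lib$expected_mz <= 0))
    stop("standards library: expected_mz must be finite and > 0", call. = FALSE)
  key <- paste(lib$compound, lib$enantiomer)
  if (anyDuplicated(key))
    stop("standards library: duplicate entry '", key[duplicated(key)][1L],
         "'", call. = FALSE)
  n_ent <- table(lib$compound[lib$enantiomer != "achiral"])
  if (any(n_ent > 2))
    stop("standards library: compound '", names(n_ent)[n_ent > 2][1L],
         "' has more than two enantiomer entries", call. = FALSE)
  class(lib) <- c("StandardsLibrary", "data.frame")
  lib
}

#' Read a gene expression matrix (TPM)
#'
#' Tab-separated genes x samples table; first column is the gene symbol.
#'
#' @param path TSV file.
#' @return Numeric matrix (genes x samples) with gene symbols as rownames.
#' @export
read_expression <- function(path) {
  raw <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2)
    stop("expression format error: need a gene column plus >= 1 sample",
         call. = FALSE)
  genes <- as.character(raw[[1L]])
  if (anyDuplicated(genes))
    stop("expression validation error: duplicate gene symbol '",
         genes[duplicated(genes)][1L], "'", call. = FALSE)
  m <- as.matrix(raw[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  if (any(!is.finite(m)))
    stop("expression validation error: non-finite TPM values", call. = FALSE)
  bad <- which(m < 0, arr.ind = TRUE)
  if (nrow(bad))
    stop("expression validation error: negative TPM for gene '",
         genes[bad[1L, 1L]], "'", call. = FALSE)
  m
}

#' Write an expression matrix as TSV
#' @param expr genes x samples numeric matrix with rownames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(gene = rownames(expr),
                   format(expr, digits = 15, trim = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read pathway definitions from a GMT file
#'
#' Standard GMT dialect: one pathway per line, `>= 3` tab-separated fields
#' (id, description, then members). Compound members are distinguished from
#' gene members by a `cpd:` prefix on the token; everything else is a gene
#' symbol.
#'
#' @param path GMT file.
#' @param topology optional edge-list file (TSV `node_a`, `node_b`,
#'   optionally `pathway_id`) attaching an undirected topology to pathways.
#' @return Named list of pathway definitions, each a list with fields
#'   `pathway_id`, `name`, `gene_members`, `compound_members`, `topology`.
#' @export
read_gmt <- function(path, topology = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  pw <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L)
      stop("GMT format error at line ", i, ": fewer than 3 fields",
           call. = FALSE)
    members <- unique(fields[-(1:2)])
    members <- members[nzchar(members)]
    is_cmpd <- startsWith(members, "cpd:")
    pw[[fields[1L]]] <- list(
      pathway_id = fields[1L],
      name = fields[2L],
      gene_members = members[!is_cmpd],
      compound_members = sub("^cpd:", "", members[is_cmpd]),
      topology = NULL
    )
  }
  if (!is.null(topology)) {
    edges <- utils::read.delim(topology, stringsAsFactors = FALSE)
    if (!all(c("node_a", "node_b") %in% names(edges)))
      stop("topology format error: need columns node_a, node_b", call. = FALSE)
    if (!"pathway_id" %in% names(edges))
      stop("topology format error: need a pathway_id column to attach edges",
           call. = FALSE)
    for (pid in unique(edges$pathway_id)) {
      if (!pid %in% names(pw)) next
      e <- edges[edges$pathway_id == pid, c("node_a", "node_b")]
      pw[[pid]]$topology <- e
      pw[[pid]] <- validate_pathway(pw[[pid]])
    }
  }
  pw
}

validate_pathway <- function(p) {
  members <- c(p$gene_members, p$compound_members)
  if (!length(members))
    stop("pathway '", p$pathway_id, "': no members", call. = FALSE)
  if (!is.null(p$topology)) {
    nodes <- unique(c(p$topology$node_a, p$topology$node_b))
    stray <- setdiff(nodes, members)
    if (length(stray))
      stop("pathway '", p$pathway_id, "': topology node '", stray[1L],
           "' is not a member", call. = FALSE)
  }
  p
}

#' Write pathway definitions as GMT (plus optional edge list)
#' @param pathways list as returned by [read_gmt()].
#' @param path output GMT path.
#' @param topology_path optional output edge-list TSV.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(pathways, path, topology_path = NULL) {
  lines <- vapply(pathways, function(p) {
    paste(c(p$pathway_id, p$name, p$gene_members,
            paste0("cpd:", p$compound_members)), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  if (!is.null(topology_path)) {
    edges <- do.call(rbind, lapply(pathways, function(p) {
      if (is.null(p$topology)) return(NULL)
      cbind(pathway_id = p$pathway_id, p$topology)
    }))
    if (is.null(edges))
      edges <- data.frame(pathway_id = character(), node_a = character(),
                          node_b = character())
    utils::write.table(edges, topology_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Write analysis results and a run manifest
#'
#' Writes each data.frame in `results` to `<dir>/<name>.csv` and a
#' `manifest.json` echoing the configuration, seed, software version and
#' per-stage record counts, so that a run is auditable and reproducible.
#'
#' @param results named list of data.frames.
#' @param dir output directory (created if needed).
#' @param config the `chiralome_config` used.
#' @param counts named list/vector of per-stage record counts.
#' @param inputs optional named character vector of input files; their md5
#'   digests are recorded.
#' @return Path of the manifest, invisibly.
#' @export
write_results <- function(results, dir, config, counts = list(),
                          inputs = character()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(results)) {
    utils::write.csv(results[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  digests <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  manifest <- list(
    software = "chiralome",
    version = as.character(utils::packageVersion("chiralome")),
    seed = config$seed,
    config = unclass(config),
    input_digests = digests,
    counts = counts,
    note = "p-values are raw (unadjusted); no multiple-testing correction applied"
  )
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(mp)
}

#' Read a run manifest
#' @param path manifest.json path.
#' @return List; `$config` is restored as a `chiralome_config`.
#' @export
read_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  m$config <- do.call(analysis_config, m$config)
  m
}
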