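#' Read a viability plate from CSV
#'
#' Expected dialect: comma separator, dot decimal, UTF-8, header row
#' with columns `dose`, `unit`, `od`, `replicate`, `role`
#' (treated|vehicle|blank) and `drug`, one row per well. Malformed
#' rows are reported with their file line number.
#'
#' @param path CSV file path.
#' @return A [viability_plate()].
#' @export
read_plate_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character", fileEncoding = "UTF-8",
                        strip.white = TRUE)
  need <- c("dose", "unit", "od", "replicate", "role", "drug")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("%s: missing column(s): %s", path, paste(miss, collapse = ", ")),
         call. = FALSE)
  line <- seq_len(nrow(df)) + 1L  # header is line 1
  num <- function(col) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v))
    if (length(bad))
      stop(sprintf("%s: non-numeric %s at line %s", path, col,
                   paste(line[bad], collapse = ", ")), call. = FALSE)
    v
  }
  dose <- num("dose"); od <- num("od"); repl <- num("replicate")
  bad_role <- which(!df$role %in% c("treated", "vehicle", "blank"))
  if (length(bad_role))
    stop(sprintf("%s: invalid role at line %s", path,
                 paste(line[bad_role], collapse = ", ")), call. = FALSE)
  units <- unique(df$unit)
  canon <- unique(vapply(units, function(u) parse_conc_unit(u)$canonical, ""))
  if (length(canon) != 1)
    stop(sprintf("%s: all wells of one plate must share one unit (found: %s)",
                 path, paste(units, collapse = ", ")), call. = FALSE)
  drug <- unique(df$drug)
  if (length(drug) != 1)
    stop(sprintf("%s: one plate holds one drug (found: %s)", path,
                 paste(drug, collapse = ", ")), call. = FALSE)
  viability_plate(dose = dose, od = od, replicate = repl, role = df$role,
                  drug = drug, unit = canon)
}

#' Write a viability plate to CSV
#'
#' Inverse of [read_plate_csv()]; the write/read round trip preserves
#' all well values.
#'
#' @param plate A [viability_plate()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_plate_csv <- function(plate, path) {
  df <- data.frame(dose = plate$dose, unit = attr(plate, "unit"),
                   od = plate$od, replicate = plate$replicate,
                   role = plate$role, drug = attr(plate, "drug"),
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a combination design table from CSV
#'
#' Columns: `cell_line`, `drug_a`, `dose_a`, `unit_a`, `drug_b`,
#' `dose_b`, `unit_b`, one row per design point.
#'
#' @param path CSV file path.
#' @return Data frame with numeric doses and validated units.
#' @export
read_combination_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character", fileEncoding = "UTF-8",
                        strip.white = TRUE)
  need <- c("cell_line", "drug_a", "dose_a", "unit_a", "drug_b", "dose_b", "unit_b")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("%s: missing column(s): %s", path, paste(miss, collapse = ", ")),
         call. = FALSE)
  line <- seq_len(nrow(df)) + 1L
  for (col in c("dose_a", "dose_b")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) | v <= 0)
    if (length(bad))
      stop(sprintf("%s: non-positive or non-numeric %s at line %s", path, col,
                   paste(line[bad], collapse = ", ")), call. = FALSE)
    df[[col]] <- v
  }
  for (col in c("unit_a", "unit_b"))
    df[[col]] <- vapply(df[[col]], function(u) parse_conc_unit(u)$canonical, "")
  df
}

#' Read an expression cohort from CSV
#'
#' First column `sample`; clinical annotation columns are prefixed
#' `clin:`; all remaining columns are genes with 2log values.
#'
#' @param path CSV file path.
#' @return A [cohort_matrix()].
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8",
                        colClasses = "character", strip.white = TRUE)
  if (names(df)[1] != "sample")
    stop(path, ": first column must be 'sample'", call. = FALSE)
  clin <- grep("^clin:", names(df), value = TRUE)
  genes <- setdiff(names(df), c("sample", clin))
  if (!length(genes)) stop(path, ": no gene columns", call. = FALSE)
  expr <- sapply(genes, function(g) {
    v <- suppressWarnings(as.numeric(df[[g]]))
    bad <- which(is.na(v) & !df[[g]] %in% c("NA", ""))
    if (length(bad))
      stop(sprintf("%s: non-numeric expression for %s at line %s", path, g,
                   paste(bad + 1L, collapse = ", ")), call. = FALSE)
    v
  })
  expr <- matrix(expr, nrow = nrow(df), dimnames = list(df$sample, genes))
  ann <- df[, clin, drop = FALSE]
  names(ann) <- sub("^clin:", "", names(ann))
  ann$sample <- df$sample
  cohort_matrix(expr, ann)
}

#' Write an expression cohort to CSV
#' @param cohort A [cohort_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  ann <- cohort$annotations
  clin <- setdiff(names(ann), "sample")
  out <- data.frame(sample = rownames(cohort$expression),
                    stringsAsFactors = FALSE, check.names = FALSE)
  for (cl in clin) out[[paste0("clin:", cl)]] <- ann[[cl]]
  for (g in colnames(cohort$expression)) out[[g]] <- cohort$expression[, g]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a receptor structure from a PDB file
#'
#' Parses ATOM (and, for a named ligand, HETATM) records of model 1.
#' Hydrogens are dropped (contact conventions here are heavy-atom
#' style and crystal structures typically lack them), waters and
#' non-ligand heteroatoms are excluded, and for alternate-location
#' atoms the highest-occupancy copy is kept.
#'
#' @param path PDB file.
#' @param chains Optional chain filter (character vector).
#' @param ligand Optional HETATM residue name whose coordinates are
#'   returned separately as a pose matrix.
#' @return A [structure_model()]; when `ligand` is given, a list with
#'   `structure` and `ligand` (n x 3 matrix).
#' @export
read_structure_pdb <- function(path, chains = NULL, ligand = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                          verbose = FALSE))
  at <- pdb$atom
  at <- at[!(at$resid %in% c("HOH", "WAT", "H2O", "DOD")), , drop = FALSE]
  elem <- at$elesy
  elem[is.na(elem) | elem == ""] <- substr(trimws(at$elety[is.na(elem) | elem == ""]), 1, 1)
  at <- at[toupper(trimws(elem)) != "H", , drop = FALSE]
  # alternate locations: keep the highest-occupancy copy of each atom
  altkey <- paste(at$chain, at$resno, at$elety, sep = "\r")
  if (anyDuplicated(altkey)) {
    occ <- at$o; occ[is.na(occ)] <- 1
    at <- at[order(altkey, -occ), , drop = FALSE]
    at <- at[!duplicated(paste(at$chain, at$resno, at$elety, sep = "\r")), , drop = FALSE]
    at <- at[order(as.integer(rownames(at))), , drop = FALSE]
  }
  lig_xyz <- NULL
  if (!is.null(ligand)) {
    lg <- at[at$resid == ligand, , drop = FALSE]
    if (nrow(lg) == 0) stop("ligand '", ligand, "' not found", call. = FALSE)
    lig_xyz <- unname(as.matrix(lg[, c("x", "y", "z")]))
    at <- at[at$resid != ligand, , drop = FALSE]
  }
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (!is.null(chains)) at <- at[at$chain %in% chains, , drop = FALSE]
  if (nrow(at) == 0) stop(path, ": no atoms left after filtering", call. = FALSE)
  sm <- structure_model(data.frame(
    chain = at$chain, resno = at$resno, resname = at$resid,
    elety = trimws(at$elety), x = at$x, y = at$y, z = at$z,
    stringsAsFactors = FALSE))
  if (is.null(ligand)) sm else list(structure = sm, ligand = lig_xyz)
}

# Fixed-column PDB ATOM/HETATM record (name cols 13-16, resName 18-20,
# chain 22, resSeq 23-26, x/y/z 31-54, element 77-78).
.pdb_atom_line <- function(serial, elety, resname, chain, resno, x, y, z,
                           record = "ATOM") {
  name <- if (nchar(elety) < 4) sprintf(" %-3s", elety) else elety
  sprintf("%-6s%5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name, resname, chain, resno, x, y, z, 1.0, 0.0,
          substr(trimws(elety), 1, 1))
}

#' Write a structure model to a PDB file
#'
#' Deterministic single-model PDB writer; round-trips through
#' [read_structure_pdb()].
#'
#' @param structure A [structure_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(structure, path) {
  a <- structure$atoms
  lines <- vapply(seq_len(nrow(a)), function(i)
    .pdb_atom_line(i, a$elety[i], a$resname[i], a$chain[i], a$resno[i],
                   a$x[i], a$y[i], a$z[i]), "")
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Write a pose ensemble as a multi-model PDB plus an energy CSV
#'
#' Each pose becomes one MODEL of carbon pseudo-atoms; energies go to a
#' two-column CSV (`model`, `energy`).
#'
#' @param ensemble A [pose_ensemble()].
#' @param path Output PDB path.
#' @param energies_path Optional CSV path for the energies (default:
#'   `path` with extension `.energies.csv`).
#' @return `path`, invisibly.
#' @export
write_pose_pdb <- function(ensemble, path,
                           energies_path = paste0(path, ".energies.csv")) {
  out <- character(0)
  for (m in seq_along(ensemble$poses)) {
    p <- ensemble$poses[[m]]
    out <- c(out, sprintf("MODEL     %4d", m),
             vapply(seq_len(nrow(p)), function(i)
               .pdb_atom_line(i, paste0("C", i), substr(ensemble$ligand_label, 1, 3),
                              "L", 1L, p[i, 1], p[i, 2], p[i, 3],
                              record = "HETATM"), ""),
             "ENDMDL")
  }
  writeLines(c(out, "END"), path)
  utils::write.csv(data.frame(model = seq_along(ensemble$poses),
                              energy = ensemble$energies),
                   energies_path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a pose ensemble from a multi-model PDB and an energy CSV
#'
#' @param path Multi-model PDB file (one MODEL per pose).
#' @param energies_path CSV with columns `model`, `energy` (or a
#'   numeric vector of energies via `energies`).
#' @param energies Optional numeric energies, one per model, used
#'   instead of the CSV.
#' @param ligand_label Label for the ensemble.
#' @return A [pose_ensemble()].
#' @export
read_pose_pdb <- function(path, energies_path = paste0(path, ".energies.csv"),
                          energies = NULL, ligand_label = "LIG") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  starts <- grep("^MODEL", lines)
  ends <- grep("^ENDMDL", lines)
  if (length(starts) == 0 || length(starts) != length(ends))
    stop(path, ": not a well-formed multi-model PDB", call. = FALSE)
  poses <- lapply(seq_along(starts), function(k) {
    blk <- lines[(starts[k] + 1):(ends[k] - 1)]
    blk <- blk[grepl("^(ATOM|HETATM)", blk)]
    if (!length(blk)) stop(path, ": empty MODEL block ", k, call. = FALSE)
    matrix(c(as.numeric(substr(blk, 31, 38)),
             as.numeric(substr(blk, 39, 46)),
             as.numeric(substr(blk, 47, 54))), ncol = 3)
  })
  if (is.null(energies)) {
    if (!file.exists(energies_path))
      stop("energies file not found: ", energies_path, call. = FALSE)
    e <- utils::read.csv(energies_path)
    if (!all(c("model", "energy") %in% names(e)))
      stop(energies_path, ": need columns model, energy", call. = FALSE)
    energies <- e$energy[order(e$model)]
  }
  pose_ensemble(poses, energies, ligand_label = ligand_label)
}

#' Write a combination-index report as TSV
#'
#' Mirrors the layout of a combination-treatment summary table:
#' columns `cell_line`, `equiv_a`, `equiv_b`, `ci`, `class`, `dose_a`,
#' `dose_b`. Numeric cells are displayed at 3 decimals with half-up
#' rounding; the underlying computation is always on unrounded values.
#' Rows keep input order; re-running is byte-identical.
#'
#' @param results A `combination_index_result` data frame (from
#'   [synergy_table()] or [ci_from_doses()]).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_synergy_report <- function(results, path) {
  fmt <- function(x) ifelse(is.na(x), "NA",
                            formatC(round_half_up(x, 3), format = "f", digits = 3))
  header <- c("cell_line", "equiv_a", "equiv_b", "ci", "class", "dose_a", "dose_b")
  if (nrow(results) == 0) {
    writeLines(paste(header, collapse = "\t"), path)
    return(invisible(path))
  }
  body <- vapply(seq_len(nrow(results)), function(i) {
    paste(c(as.character(results$cell_line[i]),
            fmt(results$e_a[i]), fmt(results$e_b[i]), fmt(results$ci[i]),
            results$synergy_class[i],
            fmt(results$dose_a[i]), fmt(results$dose_b[i])), collapse = "\t")
  }, "")
  writeLines(c(paste(header, collapse = "\t"), body), path)
  invisible(path)
}

#' Assemble and validate a run configuration
#'
#' Central defaults for the pipeline: 3.6 A contact cutoff, top 50
#' poses, 50% effect level, the standard CI band table, variable-slope
#' fitting, and bootstrap settings.
#'
#' @param contact_cutoff Contact distance, Angstrom.
#' @param top_k Poses kept for consensus scoring.
#' @param region_threshold,bridge_gap Pocket segmentation parameters.
#' @param effect_level Percent effect level for CI.
#' @param bands CI band table ([ci_bands()] layout).
#' @param variable_slope Fit the Hill slope freely.
#' @param n_boot Bootstrap replicates for IC50 intervals.
#' @param seed Integer seed.
#' @param log_level One of `"quiet"`, `"info"`, `"debug"`.
#' @return A validated `run_config` list.
#' @export
run_config <- function(contact_cutoff = 3.6, top_k = 50,
                       region_threshold = 0.5, bridge_gap = 2,
                       effect_level = 50, bands = ci_bands(),
                       variable_slope = TRUE, n_boot = 0, seed = 1,
                       log_level = "info") {
  stopifnot(is.numeric(contact_cutoff), length(contact_cutoff) == 1, contact_cutoff > 0)
  stopifnot(is.numeric(top_k), top_k >= 1)
  stopifnot(region_threshold > 0, region_threshold <= 1)
  stopifnot(bridge_gap >= 0)
  stopifnot(effect_level > 0, effect_level < 100)
  stopifnot(all(c("lower", "upper", "class") %in% names(bands)))
  stopifnot(is.logical(variable_slope), n_boot >= 0)
  if (!log_level %in% c("quiet", "info", "debug"))
    stop("log_level must be quiet, info or debug", call. = FALSE)
  cfg <- list(contact_cutoff = contact_cutoff, top_k = as.integer(top_k),
              region_threshold = region_threshold,
              bridge_gap = as.integer(bridge_gap),
              effect_level = effect_level, bands = bands,
              variable_slope = variable_slope, n_boot = as.integer(n_boot),
              seed = as.integer(seed), log_level = log_level)
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from YAML
#'
#' Keys mirror [run_config()] arguments; omitted keys keep their
#' defaults, unknown keys are an error.
#'
#' @param path YAML file path.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop(path, ": unknown config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  do.call(run_config, vals)
}
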