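#' Generate a synthetic viability plate
#'
#' Simulates an MTS-style plate read: true percent viability follows
#' the normalized logistic model at the planted IC50 and Hill slope,
#' raw OD is `baseline_od * response/100` plus additive Gaussian plate
#' noise, and vehicle (and optional blank) wells are included so the
#' plate can be normalized exactly like a measured one. Default doses
#' are seven log-spaced concentrations bracketing the planted IC50,
#' with six replicate wells per dose (three independent experiments in
#' duplicate is the usual design this emulates). Output is a pure
#' function of the arguments including `seed`.
#'
#' @param ic50 Planted IC50, in `unit`.
#' @param hill Planted Hill slope (> 0 for an inhibitor).
#' @param doses Treated doses; default seven log-spaced doses over
#'   IC50 x 10^±1.5.
#' @param replicates Wells per dose.
#' @param noise_sd Additive OD noise, as percent of the vehicle OD.
#' @param baseline_od Mean vehicle OD.
#' @param n_blank Number of blank wells (0 for none).
#' @param blank_od Mean blank OD.
#' @param drug,unit Labels for the plate.
#' @param seed Integer seed.
#' @return A [viability_plate()].
#' @export
gen_viability_plate <- function(ic50, hill = 1, doses = NULL, replicates = 6,
                                noise_sd = 2, baseline_od = 1.0,
                                n_blank = 0, blank_od = 0.05,
                                drug = "drugA", unit = "uM", seed = 1) {
  if (noise_sd < 0) stop("`noise_sd` must be non-negative", call. = FALSE)
  if (is.null(doses))
    doses <- ic50 * 10^seq(-1.5, 1.5, length.out = 7)
  if (length(doses) < 3) stop("need at least 3 doses", call. = FALSE)
  with_seed(seed, {
    sd_od <- baseline_od * noise_sd / 100
    true_resp <- .logistic_response(log10(doses), log10(ic50), hill)
    dose_col <- rep(doses, each = replicates)
    resp_col <- rep(true_resp, each = replicates)
    od_treated <- baseline_od * resp_col / 100 + stats::rnorm(length(dose_col), 0, sd_od)
    od_vehicle <- baseline_od + stats::rnorm(replicates, 0, sd_od)
    dose <- c(rep(0, replicates), dose_col)
    od <- c(od_vehicle, od_treated)
    role <- c(rep("vehicle", replicates), rep("treated", length(dose_col)))
    repl <- c(seq_len(replicates), rep(seq_len(replicates), times = length(doses)))
    if (n_blank > 0) {
      dose <- c(dose, rep(0, n_blank))
      od <- c(od, blank_od + stats::rnorm(n_blank, 0, sd_od))
      role <- c(role, rep("blank", n_blank))
      repl <- c(repl, seq_len(n_blank))
    }
    viability_plate(dose = dose, od = od, replicate = repl, role = role,
                    drug = drug, unit = unit)
  })
}

#' Generate a fixed-B/varying-A combination design with a planted CI
#'
#' For each fixed drug-B dose, drug A's true combination IC50 is set so
#' that the planted combination index holds exactly given the declared
#' single-agent IC50s: `IC50_A,comb = (CI - dose_B/IC50_B) * IC50_A`.
#' A full drug-A viability plate is then simulated at that truth. The
#' planted CI must exceed every `dose_B/IC50_B` so the implied
#' combination IC50 stays positive.
#'
#' @param ci_planted Planted combination index, > 0 (one value, or one
#'   per B dose).
#' @param ic50_a,ic50_b Declared single-agent IC50s.
#' @param b_doses Fixed drug-B doses; default five doses placing
#'   `dose_B/IC50_B` at 15--85% of the planted CI.
#' @param hill,replicates,noise_sd,baseline_od Passed to
#'   [gen_viability_plate()].
#' @param drug_a,unit_a Labels for the drug-A plates.
#' @param seed Integer seed; each plate derives its own sub-seed.
#' @return List with `plates` (one [viability_plate()] per B dose),
#'   `b_doses`, and `truth` (data frame `dose_b`, `true_ic50_a`,
#'   `planted_ci`).
#' @export
gen_combination_grid <- function(ci_planted, ic50_a, ic50_b, b_doses = NULL,
                                 hill = 1, replicates = 6, noise_sd = 2,
                                 baseline_od = 1.0, drug_a = "drugA",
                                 unit_a = "uM", seed = 1) {
  if (any(ci_planted <= 0)) stop("planted CI must be positive", call. = FALSE)
  if (is.null(b_doses))
    b_doses <- seq(0.15, 0.85, length.out = 5) * min(ci_planted) * ic50_b
  ci_planted <- rep_len(ci_planted, length(b_doses))
  e_b <- b_doses / ic50_b
  e_a <- ci_planted - e_b
  if (any(e_a <= 0))
    stop("planted CI infeasible: dose_B/IC50_B reaches or exceeds the CI",
         call. = FALSE)
  true_a <- e_a * ic50_a
  plates <- lapply(seq_along(b_doses), function(i) {
    gen_viability_plate(ic50 = true_a[i], hill = hill, replicates = replicates,
                        noise_sd = noise_sd, baseline_od = baseline_od,
                        drug = drug_a, unit = unit_a,
                        seed = seed * 1000L + i)
  })
  list(plates = plates, b_doses = b_doses,
       truth = data.frame(dose_b = b_doses, true_ic50_a = true_a,
                          planted_ci = ci_planted))
}

#' Generate a synthetic clinical expression cohort
#'
#' Draws 2log expression values from normal distributions. The target
#' gene is shifted upward by `shift_sd` standard deviations in the
#' second clinical group (emulating higher expression in the
#' poor-outcome group); the partner gene is built to have a target
#' Pearson correlation with the target gene via the bivariate-normal
#' construction `g2 = r*z1 + sqrt(1-r^2)*z2` (the group shift adds a
#' small amount of extra correlation when both are nonzero). Additional
#' independent noise genes and age/INSS annotations fill out the
#' cohort.
#'
#' @param n_per_group Named integer vector of group sizes for the
#'   grouping annotation (default MYCN status).
#' @param group_col Annotation column the shift acts on.
#' @param shift_sd Planted shift, in SD units, added to the target gene
#'   in the *last* group of `n_per_group`.
#' @param target_r Planted correlation between `target_gene` and
#'   `partner_gene` (|r| < 1).
#' @param target_gene,partner_gene Gene names.
#' @param base_mean,base_sd Mean and SD of the 2log values.
#' @param n_noise_genes Extra independent genes.
#' @param seed Integer seed.
#' @return A [cohort_matrix()].
#' @export
gen_cohort <- function(n_per_group = c(`not amplified` = 500, amplified = 149),
                       group_col = "mycn", shift_sd = 0, target_r = 0,
                       target_gene = "SPR", partner_gene = "ODC1",
                       base_mean = 8, base_sd = 1, n_noise_genes = 3,
                       seed = 1) {
  if (abs(target_r) >= 1) stop("|target_r| must be < 1", call. = FALSE)
  if (any(n_per_group <= 0)) stop("group sizes must be positive", call. = FALSE)
  n <- sum(n_per_group)
  with_seed(seed, {
    grp <- rep(names(n_per_group), n_per_group)
    z1 <- stats::rnorm(n)
    z2 <- stats::rnorm(n)
    shift <- ifelse(grp == names(n_per_group)[length(n_per_group)], shift_sd, 0)
    g1 <- base_mean + base_sd * (z1 + shift)
    g2 <- base_mean + base_sd * (target_r * z1 + sqrt(1 - target_r^2) * z2)
    expr <- cbind(g1, g2)
    colnames(expr) <- c(target_gene, partner_gene)
    if (n_noise_genes > 0) {
      noise <- matrix(stats::rnorm(n * n_noise_genes, base_mean, base_sd),
                      nrow = n)
      colnames(noise) <- sprintf("GENE%02d", seq_len(n_noise_genes))
      expr <- cbind(expr, noise)
    }
    rownames(expr) <- sprintf("S%04d", seq_len(n))
    ann <- data.frame(sample = rownames(expr), stringsAsFactors = FALSE)
    ann[[group_col]] <- grp
    if (group_col != "age_group")
      ann$age_group <- sample(c("<18mo", ">=18mo"), n, replace = TRUE)
    if (group_col != "inss_stage")
      ann$inss_stage <- sample(c("1", "2", "3", "4", "4S"), n, replace = TRUE,
                               prob = c(0.2, 0.15, 0.2, 0.35, 0.1))
    cohort_matrix(expr, ann)
  })
}

#' Generate a synthetic receptor with a planted ligand pocket
#'
#' Builds a pseudo-protein of `n_residues` residues (three heavy atoms
#' each) laid out along an extended chain so that sequence neighbors
#' are spatial neighbors and distant residues cannot touch the ligand.
#' A contiguous run of residues is designated the pocket; the reference
#' ligand is placed alongside the pocket atoms within contact range.
#' Poses are rigid copies of the reference ligand displaced by random
#' translations of length up to `jitter`; docking energies increase
#' with the displacement (plus small noise), so low-energy poses sit
#' closest to the planted site.
#'
#' @param n_residues Number of residues, chain A.
#' @param pocket_start First residue of the planted pocket (default
#'   mid-chain).
#' @param pocket_size Number of pocket residues.
#' @param n_poses Number of poses.
#' @param jitter Maximum rigid displacement in Angstrom (0 gives
#'   identical poses).
#' @param contact_offset Distance from the pocket atoms to the
#'   reference ligand atoms (default 2.5 A, inside a 3.6 A cutoff).
#' @param seed Integer seed.
#' @return List with `structure` (a [structure_model()]), `ensemble`
#'   (a [pose_ensemble()]), and `truth` (data frame of pocket
#'   residues).
#' @export
gen_pose_ensemble <- function(n_residues = 120, pocket_start = NULL,
                              pocket_size = 8, n_poses = 60, jitter = 0.5,
                              contact_offset = 2.5, seed = 1) {
  if (pocket_size > n_residues)
    stop("pocket larger than the structure", call. = FALSE)
  if (is.null(pocket_start))
    pocket_start <- max(1L, as.integer(n_residues / 2 - pocket_size / 2))
  if (pocket_start + pocket_size - 1 > n_residues)
    stop("pocket extends past the last residue", call. = FALSE)
  spacing <- 6  # A between consecutive residues: > cutoff, no spurious contacts
  atoms <- do.call(rbind, lapply(seq_len(n_residues), function(i) {
    cx <- i * spacing
    data.frame(chain = "A", resno = i, resname = "ALA",
               elety = c("N", "CA", "C"),
               x = cx + c(-1.2, 0, 1.2), y = c(0.4, 0, 0.4), z = 0,
               stringsAsFactors = FALSE)
  }))
  str <- structure_model(atoms)
  pocket <- seq(pocket_start, pocket_start + pocket_size - 1)
  # one ligand atom alongside each pocket residue's CA, offset in +y
  ca <- atoms[atoms$resno %in% pocket & atoms$elety == "CA", c("x", "y", "z")]
  ref <- as.matrix(ca)
  ref[, 2] <- ref[, 2] + contact_offset
  with_seed(seed, {
    disp <- matrix(stats::rnorm(n_poses * 3), ncol = 3)
    disp <- disp / pmax(sqrt(rowSums(disp^2)), 1e-12) *
      stats::runif(n_poses, 0, 1) * jitter
    poses <- lapply(seq_len(n_poses), function(k)
      sweep(ref, 2, disp[k, ], "+"))
    mag <- sqrt(rowSums(disp^2))
    energies <- -100 + 20 * mag + stats::rnorm(n_poses, 0, 0.01 * max(jitter, 1e-6))
    if (jitter == 0) energies <- rep(-100, n_poses)
    ens <- pose_ensemble(poses, energies, ligand_label = "LIG")
    truth <- structure_residues(str)
    truth <- truth[truth$resno %in% pocket, ]
    rownames(truth) <- NULL
    list(structure = str, ensemble = ens, truth = truth)
  })
}
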