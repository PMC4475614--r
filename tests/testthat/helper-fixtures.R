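# Noiseless normalized responses from a known logistic truth; the
# canonical input for fit-recovery checks.
noiseless_points <- function(ic50, hill = 1, doses = ic50 * 10^seq(-1.5, 1.5, length.out = 7)) {
  data.frame(dose = doses,
             response = 100 / (1 + 10^((log10(doses) - log10(ic50)) * hill)))
}

# A small random structure + pose pair for contact-detection fixtures.
random_contact_fixture <- function(n_atoms = 500, n_pose = 20, box = 40) {
  atoms <- data.frame(
    chain = "A",
    resno = rep(seq_len(ceiling(n_atoms / 4)), each = 4)[seq_len(n_atoms)],
    resname = "ALA",
    elety = rep(c("N", "CA", "C", "O"), length.out = n_atoms),
    x = runif(n_atoms, 0, box), y = runif(n_atoms, 0, box),
    z = runif(n_atoms, 0, box), stringsAsFactors = FALSE)
  pose <- cbind(runif(n_pose, 0, box), runif(n_pose, 0, box), runif(n_pose, 0, box))
  list(structure = structure_model(atoms), pose = pose)
}

# Independent all-pairs contact oracle: loops over every
# (protein atom, ligand atom) pair with plain dist() arithmetic.
oracle_contact_resnos <- function(structure, pose, cutoff) {
  a <- structure$atoms
  hit <- logical(nrow(a))
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(pose))) {
      d <- sqrt(sum((c(a$x[i], a$y[i], a$z[i]) - pose[j, ])^2))
      if (d <= cutoff) { hit[i] <- TRUE; break }
    }
  }
  sort(unique(a$resno[hit]))
}

# A random rigid-body transform (rotation + translation).
random_rigid_transform <- function() {
  q <- matrix(rnorm(9), 3)
  rot <- qr.Q(qr(q))
  if (det(rot) < 0) rot[, 1] <- -rot[, 1]
  shift <- rnorm(3, sd = 20)
  function(xyz) sweep(as.matrix(xyz) %*% rot, 2, shift, "+")
}

apply_transform_structure <- function(structure, tf) {
  a <- structure$atoms
  xyz <- tf(as.matrix(a[, c("x", "y", "z")]))
  a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
  structure_model(a)
}
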