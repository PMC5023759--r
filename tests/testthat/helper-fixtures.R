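# Shared fixtures, built in code at test time.

# default idealized monomer (cached per test run; building it is ~0.3 s)
fixture_monomer <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_ideal_tm_bundle()
    cache
  }
})

# monomer with the TM4/TM5 planted decoration
fixture_patched <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- plant_interface_patch(build_ideal_tm_bundle(), patch_spec())
    }
    cache
  }
})

# end-to-end pipeline runs on the planted-TM4/TM5 monomer, cached so the
# consensus and acceptance tests share one computation: full 12 x 12 grid,
# 10 replicates per pose, default Monte Carlo settings, five fixed seeds
recovery_runs <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      mono <- fixture_patched()
      poses <- enumerate_dimer_poses(mono, 12, 12, 4.0)
      cache <<- lapply(1:5, function(s) {
        ref <- refine_poses(poses, n_outputs = 10, mc_steps = 200,
                            seed = s * 1000 + 1)
        list(seed = s * 1000 + 1, n_poses = length(poses),
             n_refined = length(ref),
             records = normalize_scores(score_poses(ref)))
      })
    }
    cache
  }
})

# tiny hand-made structure: one chain, explicit atoms
toy_structure <- function(xyz, names = NULL, resno = NULL, chain = "A",
                          resname = "ALA", elem = NULL, charge = 0,
                          segments = NULL, bw_refs = NULL) {
  n <- nrow(xyz)
  at <- data.frame(
    name = names %||% rep("CA", n),
    resname = rep_len(resname, n),
    resno = resno %||% seq_len(n),
    chain = rep_len(chain, n),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    charge = rep_len(charge, n),
    stringsAsFactors = FALSE)
  if (!is.null(elem)) at$elem <- elem
  pdb_structure(at, segments = segments, bw_refs = bw_refs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random rigid transform (proper rotation + translation), seeded by caller
random_rigid <- function() {
  ang <- runif(3, 0, 2 * pi)
  Rz <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3)
  Ry <- function(t) matrix(c(cos(t), 0, -sin(t), 0, 1, 0, sin(t), 0, cos(t)), 3)
  list(R = Rz(ang[1]) %*% Ry(ang[2]) %*% Rz(ang[3]),
       t = runif(3, -20, 20))
}

apply_rigid <- function(m, tr) sweep(m %*% t(tr$R), 2, tr$t, "+")
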