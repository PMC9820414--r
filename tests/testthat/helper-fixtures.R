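# Small fixture builders; everything is constructed in code.

# minimal protein topology: one CA-like atom per residue unless a full
# atom table is supplied
toy_topology <- function(n_res = 5, chain = "A", names = "CA",
                         res_name = "ALA") {
  per <- length(names)
  topology(data.frame(
    serial = seq_len(n_res * per),
    name = rep(names, n_res),
    element = rep(substr(names, 1, 1), n_res),
    res_name = res_name,
    res_seq = rep(seq_len(n_res), each = per),
    chain_id = chain))
}

# two-chain topology with one atom per residue, for interaction tests
two_chain_top <- function(spec_rows) {
  df <- do.call(rbind, lapply(spec_rows, as.data.frame))
  df$serial <- seq_len(nrow(df))
  topology(df)
}

atom_row <- function(name, element, res_name, res_seq, chain,
                     formal_charge = 0) {
  list(serial = 0L, name = name, element = element, res_name = res_name,
       res_seq = res_seq, chain_id = chain, formal_charge = formal_charge)
}

# a helical 3-atom-per-residue chain as coordinates
helix_coords <- function(n_res, x0 = 0) {
  do.call(rbind, lapply(seq_len(n_res), function(i) {
    th <- 100 * i * pi / 180
    c(x0 + 2.3 * cos(th), 2.3 * sin(th), 1.5 * i)
  }))
}

# regular hexagon ring coordinates in a given plane
hexagon <- function(center, normal, radius = 1.39) {
  normal <- normal / sqrt(sum(normal^2))
  ref <- if (abs(normal[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- ref - sum(ref * normal) * normal
  u <- u / sqrt(sum(u^2))
  v <- c(normal[2] * u[3] - normal[3] * u[2],
         normal[3] * u[1] - normal[1] * u[3],
         normal[1] * u[2] - normal[2] * u[1])
  t(vapply(0:5, function(k) {
    ang <- k * pi / 3
    center + radius * (cos(ang) * u + sin(ang) * v)
  }, numeric(3)))
}

# PHE ring residue rows (6 ring atoms)
phe_rows <- function(res_seq, chain) {
  lapply(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"), function(nm) {
    atom_row(nm, "C", "PHE", res_seq, chain)
  })
}

# small deterministic multi-model PDB text
toy_pdb_text <- function(n_models = 3, n_atoms = 5) {
  set.seed(7)
  xyz <- array(round(runif(n_atoms * 3 * n_models, -50, 50), 3),
               dim = c(n_atoms, 3, n_models))
  lines <- character()
  for (m in seq_len(n_models)) {
    lines <- c(lines, sprintf("MODEL     %4d", m))
    for (i in seq_len(n_atoms)) {
      lines <- c(lines, sprintf(
        "ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
        i, i, xyz[i, 1, m], xyz[i, 2, m], xyz[i, 3, m]))
    }
    lines <- c(lines, "ENDMDL")
  }
  c(lines, "END")
}

# hand-written energy component tables for formation-energy ledger tests:
# per-chain environment terms (-2, -1, 0.5), internal 3, chain-chain cc;
# optional membrane shift on chain A relative to the monomer
formation_fixture <- function(cc, mem_shift = 0, n_frames = 4,
                              replicas = 2) {
  dimer <- do.call(rbind, lapply(seq_len(replicas), function(r) {
    do.call(rbind, lapply(seq_len(n_frames), function(f) {
      data.frame(frame = f, time_ps = (f - 1) * 100, replica = r,
                 chain = rep(c("A", "B"), each = 5),
                 term = rep(c("membrane", "water", "ions", "internal",
                              "chain"), 2),
                 partner = c("membrane", "water", "ions", "A", "B",
                             "membrane", "water", "ions", "B", "A"),
                 energy = c(-2 + mem_shift, -1, 0.5, 3, cc,
                            -2, -1, 0.5, 3, cc))
    }))
  }))
  mono <- do.call(rbind, lapply(seq_len(replicas), function(r) {
    do.call(rbind, lapply(seq_len(n_frames), function(f) {
      data.frame(frame = f, time_ps = (f - 1) * 100, replica = r,
                 chain = "A",
                 term = c("membrane", "water", "ions", "internal"),
                 partner = c("membrane", "water", "ions", "A"),
                 energy = c(-2, -1, 0.5, 3))
    }))
  }))
  list(dimer = dimer, mono = mono)
}

# small synthetic system shared by several test files
small_system <- function(frames = 50, replicas = 2, seed = 42, ...) {
  args <- list(frames_per_replica = frames, replicas = replicas,
               n_lipids = 30, n_waters = 40, n_ions = 4, seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  generate_system(do.call(synthetic_spec, args))
}
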