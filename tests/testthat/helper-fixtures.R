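# shared builders for synthetic test inputs

# a clean mid-affinity sensorgram set; kinetics resolve within the
# injection window at every concentration
clean_sensorgrams <- function(kd = 18e-9, ru_sd = 0, seed = NULL,
                              rmax = 60, top_factor = 16,
                              drift_rate = 0) {
  simulate_sensorgram(ka = 0.02 / kd, kd_off = 0.02, rmax = rmax,
                      concentrations = kd * c(0.25, 0.5, 1, 2, 8,
                                              top_factor),
                      t_assoc = 230, t_dissoc = 120, dt = 2,
                      ru_sd = ru_sd, drift_rate = drift_rate, seed = seed)
}

# minimal stand-in for an spr_kinetics fit (QC gates only need these)
fake_fit <- function(kd_eq, kd_se = 0, rmax = 60) {
  structure(list(kd_eq = kd_eq, kd_se = kd_se, rmax = rmax,
                 ka = 1e5, kd_off = kd_eq * 1e5),
            class = "spr_kinetics")
}

# write a PDB-format file from an atom table (chain, resno, resn, name,
# x, y, z, occ, elem); used to build throwaway structures in tests
write_test_pdb <- function(atoms, path, model_blocks = NULL) {
  fmt <- function(a, serial)
    sprintf("ATOM  %5d  %-3s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            serial, a$name, if (is.null(a$alt)) " " else a$alt,
            a$resn, a$chain, a$resno, " ", a$x, a$y, a$z,
            if (is.null(a$occ)) 1 else a$occ, 10, a$elem)
  if (is.null(model_blocks)) {
    lines <- vapply(seq_along(atoms), function(i) fmt(atoms[[i]], i),
                    character(1))
  } else {
    lines <- character(0)
    for (m in seq_along(model_blocks)) {
      lines <- c(lines, sprintf("MODEL     %4d", m))
      blk <- model_blocks[[m]]
      lines <- c(lines, vapply(seq_along(blk),
                               function(i) fmt(blk[[i]], i), character(1)),
                 "ENDMDL")
    }
  }
  writeLines(c(lines, "END"), path)
  path
}

atom <- function(chain, resno, name, x, y, z, resn = "ALA", elem = "C",
                 alt = NULL, occ = NULL) {
  list(chain = chain, resno = resno, name = name, resn = resn,
       x = x, y = y, z = z, elem = elem, alt = alt, occ = occ)
}

# independent brute-force coupling energy straight from Kd values
brute_force_coupling <- function(kd_ww, kd_mw, kd_wm, kd_mm,
                                 R = 1.986e-3, T = 298) {
  (R * T) * (log(kd_mm) + log(kd_ww) - log(kd_mw) - log(kd_wm))
}
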