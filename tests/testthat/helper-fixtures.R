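# shared fixture builders (everything is generated in code; no binary data)

# two bare sulfur ions at distance d, non-periodic
two_sulfur_cell <- function(d = 2.08) {
  cell <- generate_vacuum_disulfide(d)
  cell$atoms <- cell$atoms[cell$bridge, ]
  cell$bridge <- c(1L, 2L)
  rownames(cell$atoms) <- NULL
  cell
}

# minimal PDB text with one cystine bridge (CYS 10 / CYS 20) plus extras
synthetic_cystine_pdb <- function(extra_far = TRUE) {
  atom_line <- function(serial, name, resname, resno, x, y, z, elem) {
    sprintf("ATOM  %5d %-4s %3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            serial, name, resname, resno, x, y, z, 1.0, 0.0, elem)
  }
  lines <- c(
    atom_line(1, " CB ", "CYS", 10, -1.44, 1.75, 0.00, "C"),
    atom_line(2, " SG ", "CYS", 10, -1.04, 0.00, 0.00, "S"),
    atom_line(3, " SG ", "CYS", 20,  1.04, 0.00, 0.00, "S"),
    atom_line(4, " CB ", "CYS", 20,  1.44, 0.00, 1.75, "C"),
    atom_line(5, " O  ", "HOH", 30,  3.00, 3.00, 3.00, "O"),
    atom_line(6, " N  ", "GLY", 40, -3.10, 2.00, -2.50, "N"))
  if (extra_far)
    lines <- c(lines, atom_line(7, " O  ", "HOH", 50, 40.0, 40.0, 40.0, "O"))
  c(lines, "END")
}

# fast, tiny dynamics configuration for unit tests
quick_config <- function(t_end, dt = 0.02, ...) {
  dynamics_config(dt = dt, t_end = t_end, ...)
}
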