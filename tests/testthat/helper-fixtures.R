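# Programmatic fixtures: minimal PDB text and peak-list files built in
# code at test time.

pdb_atom_line <- function(type = "ATOM", serial = 1, name = "CA",
                          alt = "", resid = "GLY", chain = "A",
                          resno = 1, x = 0, y = 0, z = 0, o = 1,
                          b = 10, elesy = NULL) {
  if (is.null(elesy))
    elesy <- toupper(substr(gsub("[0-9]", "", name), 1, 1))
  name_fmt <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          type, serial, name_fmt, alt, resid, chain, resno, " ",
          x, y, z, o, b, elesy)
}

write_pdb_fixture <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

# A two-chain poly-glycine stub: full backbone, given per-residue
# B-factors, arbitrary but valid geometry.
backbone_fixture <- function(bfactors_by_chain, path = tempfile(fileext = ".pdb")) {
  lines <- character(0)
  serial <- 0
  for (ch in names(bfactors_by_chain)) {
    bs <- bfactors_by_chain[[ch]]
    for (r in seq_along(bs)) {
      for (at in c("N", "CA", "C", "O")) {
        serial <- serial + 1
        lines <- c(lines, pdb_atom_line(
          serial = serial, name = at, resid = "GLY", chain = ch,
          resno = r, x = 3.8 * r + serial * 0.01, y = serial * 0.02,
          z = match(at, c("N", "CA", "C", "O")) * 0.5, b = bs[r]))
      }
    }
  }
  write_pdb_fixture(lines, path)
}

# CA-trace fixture from a coordinate matrix.
ca_trace_fixture <- function(xyz, chain = "A", resno = seq_len(nrow(xyz)),
                             b = 10, path = tempfile(fileext = ".pdb")) {
  b <- rep_len(b, nrow(xyz))
  lines <- vapply(seq_len(nrow(xyz)), function(i)
    pdb_atom_line(serial = i, name = "CA", resid = "GLY", chain = chain,
                  resno = resno[i], x = xyz[i, 1], y = xyz[i, 2],
                  z = xyz[i, 3], b = b[i]), character(1))
  write_pdb_fixture(lines, path)
}

write_peaklist_fixture <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

write_fasta_fixture <- function(ids, seqs, path = tempfile(fileext = ".fasta")) {
  writeLines(as.vector(rbind(paste0(">", ids), seqs)), path)
  path
}
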