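# write a minimal PDB file from a data.frame with columns:
# record, serial, name, alt, resname, chain, resno, x, y, z, occ, element
write_test_pdb <- function(df, path = tempfile(fileext = ".pdb")) {
  lines <- vapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    nm <- if (nchar(r$name) < 4) sprintf(" %-3s", r$name) else r$name
    sprintf("%-6s%5d %4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            r$record, r$serial, nm, r$alt, r$resname, r$chain, r$resno,
            r$x, r$y, r$z, r$occ, 0, r$element)
  }, character(1))
  writeLines(c(lines, "END"), path)
  path
}

pdb_row <- function(serial, name, resname, chain, resno, x, y, z,
                    element, record = "ATOM", alt = " ", occ = 1) {
  data.frame(record = record, serial = serial, name = name, alt = alt,
             resname = resname, chain = chain, resno = resno,
             x = x, y = y, z = z, occ = occ, element = element,
             stringsAsFactors = FALSE)
}

# a tiny receptor: three residues with CA + one sidechain atom each,
# plus a HETATM ligand (N + carbonyl C + methyl C with 3 H)
tiny_complex_pdb <- function(path = tempfile(fileext = ".pdb")) {
  df <- rbind(
    pdb_row(1, "CA", "ALA", "A", 1, 0, 0, 0, "C"),
    pdb_row(2, "CB", "ALA", "A", 1, 1.5, 0, 0, "C"),
    pdb_row(3, "CA", "GLY", "A", 2, 4, 0, 0, "C"),
    pdb_row(4, "CA", "SER", "A", 3, 8, 0, 0, "C"),
    pdb_row(5, "OG", "SER", "A", 3, 8, 1.4, 0, "O"),
    pdb_row(6, "N1", "LIG", "L", 10, 0, 4.0, 0, "N", record = "HETATM"),
    pdb_row(7, "C1", "LIG", "L", 10, 1.3, 4.5, 0, "C", record = "HETATM"),
    pdb_row(8, "O1", "LIG", "L", 10, 1.4, 5.7, 0, "O", record = "HETATM"),
    pdb_row(9, "C2", "LIG", "L", 10, 2.5, 3.7, 0, "C", record = "HETATM"),
    pdb_row(10, "H21", "LIG", "L", 10, 3.4, 4.3, 0, "H", record = "HETATM"),
    pdb_row(11, "H22", "LIG", "L", 10, 2.6, 3.0, 0.9, "H", record = "HETATM"),
    pdb_row(12, "H23", "LIG", "L", 10, 2.6, 3.0, -0.9, "H", record = "HETATM")
  )
  write_test_pdb(df, path)
}
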