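## Shared fixtures built in code.

CODE5 <- genetic_code(5L)

tree4 <- function() read_marked_tree("((a:0.2,b:0.3)#1:0.1,c:0.4,d:0.3);")

tree6 <- function(fg_len = 0.08) {
  read_marked_tree(sprintf(
    "(((t1:0.1,t2:0.1)#1:%g,t3:0.15):0.1,(t4:0.12,t5:0.1):0.1,t6:0.2);",
    fg_len))
}

## 10-taxon tree used for the NEB power study: a 2-taxon foreground clade on a
## short stem, with a deep outgroup structure
tree10_neb <- function() {
  read_marked_tree(paste0(
    "(((f1:0.1,f2:0.1)#1:0.1,(o1:0.3,o2:0.3):0.2):0.15,",
    "((o3:0.25,o4:0.25):0.2,(o5:0.3,o6:0.2):0.15):0.1,o7:0.4);"))
}

random_codon_matrix <- function(ntaxa, nsites, code = CODE5, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(sample(code$sense, ntaxa * nsites, replace = TRUE),
                nrow = ntaxa)
    rownames(m) <- paste0("t", seq_len(ntaxa))
    m
  })
}

random_alignment <- function(ntaxa, nsites, code = CODE5, seed = 1) {
  codon_alignment(random_codon_matrix(ntaxa, nsites, code, seed),
                  code = code, strip_terminal_stop = FALSE)
}

uniform_freqs <- function(code = CODE5) {
  setNames(rep(1 / length(code$sense), length(code$sense)), code$sense)
}

## minimal hand-rolled PDB ATOM line (for reader edge cases)
pdb_atom_line <- function(serial, elety, resid, chain, resno, x, y, z,
                          occ = 1, alt = " ") {
  sprintf("ATOM  %5d  %-3s%s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           %s",
          serial, elety, alt, resid, chain, resno, x, y, z, occ, 0,
          substr(elety, 1, 1))
}
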