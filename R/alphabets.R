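# Canonical alphabets. Nucleotide sequences are stored DNA-style (U mapped to
# T); amino-acid sequences use the 20 standard one-letter codes, with an
# optional "X" unknown code when permissive canonicalization is requested.
NUC_ALPHABET <- c("A", "C", "G", "T")
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Fixed amino-acid codes: alphabetical one-letter order A..Y -> 0..19, with
# "X" (unknown) -> 20. The segment hash depends on this table being stable.
AA_CODES <- stats::setNames(c(0:19, 20L), c(AA_ALPHABET, "X"))
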