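# Fixed alphabets shared by every module.

#' Standard amino-acid alphabet
#'
#' The 20 one-letter codes of the standard proteinogenic amino acids, in
#' alphabetical order. This fixed ordering defines the column order of all
#' compositional descriptors.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

CLASS_LEVELS <- c("NON_ANTI", "ANTI")
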