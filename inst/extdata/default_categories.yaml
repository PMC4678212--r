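# Default functional-category rules for abscission transcriptomes.
# Matching is case-insensitive substring search on the gene description.
# A rule with reassign_to moves its matches out of the category named by
# `name` and into the target category (the KORRIGAN-like GH9A1 cellulases
# belong with cellulose biosynthesis, not wall disassembly).
# This keyword set is a reconstruction from annotation exemplars; edit freely.
- name: cellulases
  include:
    - cellulase
    - glycoside hydrolase family 9
    - glycoside hydrolase 9
    - endo-1,4-beta-glucanase
    - endoglucanase
  exclude:
    - cellulose synthase
- name: cellulose_biosynthesis
  include:
    - cellulose synthase
    - cesa
- name: cellulases
  include:
    - 9a1
    - korrigan
  reassign_to: cellulose_biosynthesis
- name: polygalacturonases
  include:
    - polygalacturonase
    - pectinase
    - pectate lyase
    - pectin lyase
- name: expansins
  include:
    - expansin
- name: expansins_alpha
  include:
    - alpha-expansin
    - expansin a
- name: expansins_beta
  include:
    - beta-expansin
    - expansin b
- name: xth
  include:
    - xyloglucan endotransglucosylase
    - xyloglucan endotransglycosylase
    - xyloglucan:xyloglucosyl transferase
- name: pr_genes
  include:
    - pathogenesis-related
    - thaumatin
    - chitinase
    - beta-1,3-glucanase
    - kunitz
- name: par1
  include:
    - photoassimilate-responsive
    - par1
- name: wax_suberin
  include:
    - wax
    - suberin
    - gdsl
    - lipid transfer protein
    - cer4
    - acyl coa reductase
    - fatty acid
    - lipid
- name: peroxidase_laccase
  include:
    - peroxidase
    - laccase
- name: callose_synthase
  include:
    - callose synthase
- name: wall_proteins
  include:
    - extensin
    - arabinogalactan
    - hydroxyproline-rich
    - glycine-rich cell wall
    - proline-rich cell wall
- name: ethylene_synthesis
  include:
    - aminocyclopropane
    - acc synthase
    - acc oxidase
- name: auxin
  include:
    - pin-formed
    - auxin efflux
    - gh3
    - saur
    - aux/iaa
    - auxin-responsive
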