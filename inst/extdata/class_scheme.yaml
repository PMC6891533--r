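# Ordered keyword rules for target classification (first match wins).
# Enzyme keywords precede the generic receptor fallback so that e.g.
# receptor kinases classify as enzymes; "Others" is never assigned by
# keyword, only via an explicit class_label in the target table.
rules:
  - pattern: "kinase|protease|peptidase|esterase|phosphatase|hydrolase|transferase|oxidoreductase|reductase|synthase|synthetase|polymerase|isomerase|ligase|lyase|dehydrogenase|oxidase|deaminase|carboxylase|cyclase|phosphodiesterase|enzyme"
    class: "Enzymes"
  - pattern: "G[ -]?protein[ -]coupled receptor|GPCR"
    class: "G protein-coupled receptors"
  - pattern: "nuclear receptor|transcription factor"
    class: "Transcription factors"
  - pattern: "channel"
    class: "Ion channels"
  - pattern: "solute carrier|transporter"
    class: "Transporters"
  - pattern: "receptor"
    class: "Receptors"
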