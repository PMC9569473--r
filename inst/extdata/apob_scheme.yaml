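# Segmentation of mature human apolipoprotein B-100 (preproprotein numbering;
# the 1-27 signal peptide is outside the span). Eleven domains over five
# subunits; subunit IV domain 3 is assembled from three separate stretches.
# Subunit V domain 1 is recorded with its longer extent (to Y4269); a shorter
# variant ending at I4190 has also been described for the primary model.
name: apoB-100
span: [28, 4563]
unmodeled:
  - [2551, 2590]   # excluded from the subunit IV model
  - [4056, 4057]   # last two residues of subunit IV, excluded from analysis
segments:
  - segment: "subunit I"
    level: subunit
    ranges: [[28, 1017]]
  - segment: "subunit II"
    level: subunit
    ranges: [[1018, 2072]]
  - segment: "subunit III"
    level: subunit
    ranges: [[2073, 2550]]
  - segment: "subunit IV"
    level: subunit
    ranges: [[2551, 4057]]
  - segment: "subunit V"
    level: subunit
    ranges: [[4058, 4563]]
  - segment: "subunit II coil"
    level: coil
    ranges: [[1018, 1500]]
  - segment: "subunit IV coil"
    level: coil
    ranges: [[2551, 2900]]
  - segment: "subunit II domain 1"
    level: domain
    ranges: [[1501, 2072]]
  - segment: "subunit III domain 1"
    level: domain
    ranges: [[2073, 2273]]
  - segment: "subunit III domain 2"
    level: domain
    ranges: [[2293, 2550]]   # residues 2274-2292 belong to no domain
  - segment: "subunit IV domain 1"
    level: domain
    ranges: [[2929, 3340]]
  - segment: "subunit IV domain 2"
    level: domain
    ranges: [[3380, 3717]]
  - segment: "subunit IV domain 3"
    level: domain
    ranges: [[2901, 2928], [3341, 3379], [3718, 4057]]
  - segment: "subunit V domain 1"
    level: domain
    ranges: [[4058, 4269]]
  - segment: "subunit V domain 2"
    level: domain
    ranges: [[4271, 4558]]
# Secondary-structure content per subunit as percentage of the whole
# sequence (cells of one class sum to the total content of that class).
ss_table:
  - {segment: "subunit I",   helix: 7.0,  strand: 6.5,  coil: 8.0}
  - {segment: "subunit II",  helix: 0.5,  strand: 12.5, coil: 10.5}
  - {segment: "subunit III", helix: 5.0,  strand: 0.0,  coil: 5.0}
  - {segment: "subunit IV",  helix: 1.0,  strand: 22.0, coil: 10.5}
  - {segment: "subunit V",   helix: 10.5, strand: 0.0,  coil: 1.0}
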