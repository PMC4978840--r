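# Three-class amino-acid partitions for the CTD encoders.
#
# Section order and class order are part of the feature-ordering contract:
# the 188D vector is 20 amino-acid composition values followed by one
# 21-value block per section below, laid out C1,C2,C3,T12,T13,T23, then
# five distribution values for class 1, class 2 and class 3 in turn.
#
# Each grouping must partition the 20 standard amino acids into three
# disjoint classes. Pass a file in this format via `--property-table` (CLI)
# or read_property_table() to override the defaults.

[hydrophobicity]
class1 polar        RKEDQN
class2 neutral      GASTPHY
class3 hydrophobic  CLVIMFW

[vdw_volume]
class1 small   GASTPDC
class2 medium  NVEQIL
class3 large   MHKFRYW

[polarity]
class1 low     LIFWCMVY
class2 medium  PATGS
class3 high    HQRKNED

[polarizability]
class1 low     GASDT
class2 medium  CPNVEQIL
class3 high    KMHFRYW

[charge]
class1 positive  KR
class2 neutral   ANCQGHILMFPSTWYV
class3 negative  DE

[surface_tension]
class1 low     GQDNAHR
class2 medium  KTSEC
class3 high    ILMFPWYV

[secondary_structure]
class1 helix   EALMQKRH
class2 strand  VIYCWFT
class3 coil    GNPSD

[solvent_accessibility]
class1 buried        ALFCGIVW
class2 exposed       RKQEND
class3 intermediate  MSPTHY
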