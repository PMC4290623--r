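data_cifpocket
_entry.id cifpocket

_cell.entry_id cifpocket
_cell.length_a 1
_cell.length_b 1
_cell.length_c 1
_cell.angle_alpha 90
_cell.angle_beta 90
_cell.angle_gamma 90

_symmetry.entry_id cifpocket
_symmetry.space_group_name_H-M ''

loop_
_entity.id
_entity.type
1 polymer
2 non-polymer

loop_
_entity_poly.entity_id
_entity_poly.type
_entity_poly.pdbx_strand_id
_entity_poly.pdbx_seq_one_letter_code
1 polypeptide(L) A ?



loop_
_chem_comp.id
_chem_comp.type
ALA .
GLY .
LIG .
LYS .

loop_
_struct_asym.id
_struct_asym.entity_id
Axp 1
Lx1 2



loop_
_atom_type.symbol
C
N
O


loop_
_atom_site.group_PDB
_atom_site.id
_atom_site.type_symbol
_atom_site.label_atom_id
_atom_site.label_alt_id
_atom_site.label_comp_id
_atom_site.label_asym_id
_atom_site.label_entity_id
_atom_site.label_seq_id
_atom_site.pdbx_PDB_ins_code
_atom_site.Cartn_x
_atom_site.Cartn_y
_atom_site.Cartn_z
_atom_site.occupancy
_atom_site.B_iso_or_equiv
_atom_site.pdbx_formal_charge
_atom_site.auth_atom_id
_atom_site.auth_comp_id
_atom_site.auth_seq_id
_atom_site.auth_asym_id
_atom_site.pdbx_PDB_model_num
ATOM 1 C CA . ALA Axp 1 . ? 12 0 0 1 0 ? CA ALA 1 A 1
ATOM 2 N N . GLY Axp 1 . ? 6.788 6.788 0 1 0 ? N GLY 2 A 1
ATOM 3 C CA . GLY Axp 1 . ? 8.485 8.485 0 1 0 ? CA GLY 2 A 1
ATOM 4 C CA . ALA Axp 1 . ? 0 12 0 1 0 ? CA ALA 3 A 1
ATOM 5 C CA . ALA Axp 1 . ? -8.485 8.485 0 1 0 ? CA ALA 4 A 1
ATOM 6 N NZ . LYS Axp 1 . ? -9.6 0 0 1 0 ? NZ LYS 5 A 1
ATOM 7 C CA . LYS Axp 1 . ? -12 0 0 1 0 ? CA LYS 5 A 1
ATOM 8 C CA . ALA Axp 1 . ? -8.485 -8.485 0 1 0 ? CA ALA 6 A 1
HETATM 9 O O1 . LIG Lx1 2 . ? 4.738 4.738 0 1 0 ? O1 LIG 900 L 1
HETATM 10 O O2 . LIG Lx1 2 . ? -5.8 0 0 1 0 ? O2 LIG 900 L 1
HETATM 11 C C3 . LIG Lx1 2 . ? -4.55 0 0 1 0 ? C3 LIG 900 L 1
HETATM 12 O O4 . LIG Lx1 2 . ? -3.3 0 0 1 0 ? O4 LIG 900 L 1
HETATM 13 C CAN . LIG Lx1 2 . ? 0 0 25 1 0 ? CAN LIG 900 L 1
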