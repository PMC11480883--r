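# Synthetic NMR-STAR 3.1 relaxation fixture (not a BMRB archive entry).
# Five residues with transverse 15N relaxation at two fields: one save-frame
# stores relaxation times (T2, seconds), the other stores rates (s-1).

data_synthetic_relax

save_T2_500
   _Heteronucl_T2_list.Sf_category                 heteronucl_T2_relaxation
   _Heteronucl_T2_list.Sf_framecode                T2_500
   _Heteronucl_T2_list.Spectrometer_frequency_1H   500.13
   _Heteronucl_T2_list.T2_coherence_type           Ny
   _Heteronucl_T2_list.T2_val_units                s

   loop_
      _T2.Comp_index_ID
      _T2.Comp_ID
      _T2.Val
      _T2.Val_err

      1 ALA 0.100  0.005
      2 GLY 0.125  0.006
      3 LEU 0.200  0.004
      4 SER 0.250  0.010
      5 LYS 0.500  0.020
   stop_
save_

save_R2_600
   _Heteronucl_T2_list.Sf_category                 heteronucl_T2_relaxation
   _Heteronucl_T2_list.Sf_framecode                R2_600
   _Heteronucl_T2_list.Spectrometer_frequency_1H   600.05
   _Heteronucl_T2_list.T2_coherence_type           Ny
   _Heteronucl_T2_list.T2_val_units                s-1

   loop_
      _T2.Comp_index_ID
      _T2.Comp_ID
      _T2.Val
      _T2.Val_err

      1 ALA 11.52 0.30
      2 GLY  9.21 0.30
      3 LEU  5.76 0.20
      4 SER  4.61 0.20
      5 LYS  2.30 0.10
   stop_
save_
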