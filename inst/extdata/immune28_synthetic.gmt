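Activated B cell	synthetic_marker_set	SYNMRK01_01	SYNMRK01_02	SYNMRK01_03	SYNMRK01_04	SYNMRK01_05	SYNMRK01_06	SYNMRK01_07	SYNMRK01_08	SYNMRK01_09	SYNMRK01_10
Activated CD4 T cell	synthetic_marker_set	SYNMRK02_01	SYNMRK02_02	SYNMRK02_03	SYNMRK02_04	SYNMRK02_05	SYNMRK02_06	SYNMRK02_07	SYNMRK02_08	SYNMRK02_09	SYNMRK02_10
Activated CD8 T cell	synthetic_marker_set	SYNMRK03_01	SYNMRK03_02	SYNMRK03_03	SYNMRK03_04	SYNMRK03_05	SYNMRK03_06	SYNMRK03_07	SYNMRK03_08	SYNMRK03_09	SYNMRK03_10
Activated dendritic cell	synthetic_marker_set	SYNMRK04_01	SYNMRK04_02	SYNMRK04_03	SYNMRK04_04	SYNMRK04_05	SYNMRK04_06	SYNMRK04_07	SYNMRK04_08	SYNMRK04_09	SYNMRK04_10
CD56bright natural killer cell	synthetic_marker_set	SYNMRK05_01	SYNMRK05_02	SYNMRK05_03	SYNMRK05_04	SYNMRK05_05	SYNMRK05_06	SYNMRK05_07	SYNMRK05_08	SYNMRK05_09	SYNMRK05_10
CD56dim natural killer cell	synthetic_marker_set	SYNMRK06_01	SYNMRK06_02	SYNMRK06_03	SYNMRK06_04	SYNMRK06_05	SYNMRK06_06	SYNMRK06_07	SYNMRK06_08	SYNMRK06_09	SYNMRK06_10
Central memory CD4 T cell	synthetic_marker_set	SYNMRK07_01	SYNMRK07_02	SYNMRK07_03	SYNMRK07_04	SYNMRK07_05	SYNMRK07_06	SYNMRK07_07	SYNMRK07_08	SYNMRK07_09	SYNMRK07_10
Central memory CD8 T cell	synthetic_marker_set	SYNMRK08_01	SYNMRK08_02	SYNMRK08_03	SYNMRK08_04	SYNMRK08_05	SYNMRK08_06	SYNMRK08_07	SYNMRK08_08	SYNMRK08_09	SYNMRK08_10
Effector memory CD4 T cell	synthetic_marker_set	SYNMRK09_01	SYNMRK09_02	SYNMRK09_03	SYNMRK09_04	SYNMRK09_05	SYNMRK09_06	SYNMRK09_07	SYNMRK09_08	SYNMRK09_09	SYNMRK09_10
Effector memory CD8 T cell	synthetic_marker_set	SYNMRK10_01	SYNMRK10_02	SYNMRK10_03	SYNMRK10_04	SYNMRK10_05	SYNMRK10_06	SYNMRK10_07	SYNMRK10_08	SYNMRK10_09	SYNMRK10_10
Eosinophil	synthetic_marker_set	SYNMRK11_01	SYNMRK11_02	SYNMRK11_03	SYNMRK11_04	SYNMRK11_05	SYNMRK11_06	SYNMRK11_07	SYNMRK11_08	SYNMRK11_09	SYNMRK11_10
Gamma delta T cell	synthetic_marker_set	SYNMRK12_01	SYNMRK12_02	SYNMRK12_03	SYNMRK12_04	SYNMRK12_05	SYNMRK12_06	SYNMRK12_07	SYNMRK12_08	SYNMRK12_09	SYNMRK12_10
Immature B cell	synthetic_marker_set	SYNMRK13_01	SYNMRK13_02	SYNMRK13_03	SYNMRK13_04	SYNMRK13_05	SYNMRK13_06	SYNMRK13_07	SYNMRK13_08	SYNMRK13_09	SYNMRK13_10
Immature dendritic cell	synthetic_marker_set	SYNMRK14_01	SYNMRK14_02	SYNMRK14_03	SYNMRK14_04	SYNMRK14_05	SYNMRK14_06	SYNMRK14_07	SYNMRK14_08	SYNMRK14_09	SYNMRK14_10
Macrophage	synthetic_marker_set	SYNMRK15_01	SYNMRK15_02	SYNMRK15_03	SYNMRK15_04	SYNMRK15_05	SYNMRK15_06	SYNMRK15_07	SYNMRK15_08	SYNMRK15_09	SYNMRK15_10
Mast cell	synthetic_marker_set	SYNMRK16_01	SYNMRK16_02	SYNMRK16_03	SYNMRK16_04	SYNMRK16_05	SYNMRK16_06	SYNMRK16_07	SYNMRK16_08	SYNMRK16_09	SYNMRK16_10
MDSC	synthetic_marker_set	SYNMRK17_01	SYNMRK17_02	SYNMRK17_03	SYNMRK17_04	SYNMRK17_05	SYNMRK17_06	SYNMRK17_07	SYNMRK17_08	SYNMRK17_09	SYNMRK17_10
Memory B cell	synthetic_marker_set	SYNMRK18_01	SYNMRK18_02	SYNMRK18_03	SYNMRK18_04	SYNMRK18_05	SYNMRK18_06	SYNMRK18_07	SYNMRK18_08	SYNMRK18_09	SYNMRK18_10
Monocyte	synthetic_marker_set	SYNMRK19_01	SYNMRK19_02	SYNMRK19_03	SYNMRK19_04	SYNMRK19_05	SYNMRK19_06	SYNMRK19_07	SYNMRK19_08	SYNMRK19_09	SYNMRK19_10
Natural killer cell	synthetic_marker_set	SYNMRK20_01	SYNMRK20_02	SYNMRK20_03	SYNMRK20_04	SYNMRK20_05	SYNMRK20_06	SYNMRK20_07	SYNMRK20_08	SYNMRK20_09	SYNMRK20_10
Natural killer T cell	synthetic_marker_set	SYNMRK21_01	SYNMRK21_02	SYNMRK21_03	SYNMRK21_04	SYNMRK21_05	SYNMRK21_06	SYNMRK21_07	SYNMRK21_08	SYNMRK21_09	SYNMRK21_10
Neutrophil	synthetic_marker_set	SYNMRK22_01	SYNMRK22_02	SYNMRK22_03	SYNMRK22_04	SYNMRK22_05	SYNMRK22_06	SYNMRK22_07	SYNMRK22_08	SYNMRK22_09	SYNMRK22_10
Plasmacytoid dendritic cell	synthetic_marker_set	SYNMRK23_01	SYNMRK23_02	SYNMRK23_03	SYNMRK23_04	SYNMRK23_05	SYNMRK23_06	SYNMRK23_07	SYNMRK23_08	SYNMRK23_09	SYNMRK23_10
Regulatory T cell	synthetic_marker_set	SYNMRK24_01	SYNMRK24_02	SYNMRK24_03	SYNMRK24_04	SYNMRK24_05	SYNMRK24_06	SYNMRK24_07	SYNMRK24_08	SYNMRK24_09	SYNMRK24_10
T follicular helper cell	synthetic_marker_set	SYNMRK25_01	SYNMRK25_02	SYNMRK25_03	SYNMRK25_04	SYNMRK25_05	SYNMRK25_06	SYNMRK25_07	SYNMRK25_08	SYNMRK25_09	SYNMRK25_10
Type 1 T helper cell	synthetic_marker_set	SYNMRK26_01	SYNMRK26_02	SYNMRK26_03	SYNMRK26_04	SYNMRK26_05	SYNMRK26_06	SYNMRK26_07	SYNMRK26_08	SYNMRK26_09	SYNMRK26_10
Type 17 T helper cell	synthetic_marker_set	SYNMRK27_01	SYNMRK27_02	SYNMRK27_03	SYNMRK27_04	SYNMRK27_05	SYNMRK27_06	SYNMRK27_07	SYNMRK27_08	SYNMRK27_09	SYNMRK27_10
Type 2 T helper cell	synthetic_marker_set	SYNMRK28_01	SYNMRK28_02	SYNMRK28_03	SYNMRK28_04	SYNMRK28_05	SYNMRK28_06	SYNMRK28_07	SYNMRK28_08	SYNMRK28_09	SYNMRK28_10
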