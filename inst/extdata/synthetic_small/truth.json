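{
  "positive_probs": [
    [0.0665218696827144, 0.0597272945651086, 0.0926253828445601, 0.10278508657792, 0.0311241717545791, 0.0570072265038535, 0.0669035932339105, 0.0476538484636173, 0.0467668902011811, 0.0778104293864478, 0.0194324492042839, 0.0327368231408267, 0.0382198378540687, 0.0316885997397658, 0.0445898108297468, 0.0535400260234211, 0.0431384245821239, 0.0553139425482935, 0.00886958262436193, 0.0235447102392153, 0],
    [0.0558202382143929, 0.0903372034831348, 0.117942848563707, 0.126468121309178, 0.0261171053948554, 0.0478362526273646, 0.0963590231208087, 0.0399875888299469, 0.0392433189870884, 0.0652927634871384, 0.0163062756480833, 0.0274703232909619, 0.0320712641377239, 0.0265907316584926, 0.0374164748273446, 0.0449268341507357, 0.0361985787208488, 0.0464153738364528, 0.00744269842858573, 0.0197569812831548, 0],
    [0.0379841857671905, 0.141353718346512, 0.160138624762286, 0.165939845861275, 0.0177719947953158, 0.0325512961665499, 0.145451406265639, 0.0272104894404964, 0.0267040336302672, 0.0444299869882895, 0.011095986387749, 0.0186928235411871, 0.0218236412771494, 0.0180942848563707, 0.025460914823341, 0.0305715143629266, 0.0246321689520568, 0.031584425983385, 0.00506455810229206, 0.0134440996897207, 0],
    [0.00825743168851967, 0.226381243118807, 0.230464918426584, 0.231726053448103, 0.00386347712941647, 0.00707636873185867, 0.227272044840356, 0.00591532379141227, 0.00580522470223201, 0.00965869282354118, 0.00241217095385847, 0.00406365729156241, 0.00474426984285857, 0.00393354018616755, 0.005534981483335, 0.00664598138324492, 0.00535481933740366, 0.00686617956160544, 0.00110099089180262, 0.0029226303673306, 0],
    [0.0379841857671905, 0.141353718346512, 0.160138624762286, 0.165939845861275, 0.0177719947953158, 0.0325512961665499, 0.145451406265639, 0.0272104894404964, 0.0267040336302672, 0.0444299869882895, 0.011095986387749, 0.0186928235411871, 0.0218236412771494, 0.0180942848563707, 0.025460914823341, 0.0305715143629266, 0.0246321689520568, 0.031584425983385, 0.00506455810229206, 0.0134440996897207, 0],
    [0.0558202382143929, 0.0903372034831348, 0.117942848563707, 0.126468121309178, 0.0261171053948554, 0.0478362526273646, 0.0963590231208087, 0.0399875888299469, 0.0392433189870884, 0.0652927634871384, 0.0163062756480833, 0.0274703232909619, 0.0320712641377239, 0.0265907316584926, 0.0374164748273446, 0.0449268341507357, 0.0361985787208488, 0.0464153738364528, 0.00744269842858573, 0.0197569812831548, 0],
    [0.0665218696827144, 0.0597272945651086, 0.0926253828445601, 0.10278508657792, 0.0311241717545791, 0.0570072265038535, 0.0669035932339105, 0.0476538484636173, 0.0467668902011811, 0.0778104293864478, 0.0194324492042839, 0.0327368231408267, 0.0382198378540687, 0.0316885997397658, 0.0445898108297468, 0.0535400260234211, 0.0431384245821239, 0.0553139425482935, 0.00886958262436193, 0.0235447102392153, 0]
  ],
  "ss_pos": [0.25, 0.15, 0.6],
  "ss_neg": [0.35, 0.25, 0.4],
  "rsa_pos": {
    "means": [0.25, 0.35, 0.45],
    "sd": 0.06,
    "weights": [1, 1, 1]
  },
  "rsa_neg": {
    "means": [0.15, 0.55],
    "sd": 0.18,
    "weights": [1, 1]
  },
  "spec": {
    "n_chains": 5,
    "chain_length": 100,
    "site_density": 2,
    "L": 7,
    "theta": 0.9,
    "flank_decay": 0.6,
    "preferred": ["C", "H", "D", "E"],
    "background": [0.0825743168851967, 0.0138124311880693, 0.0546491842658393, 0.0672605344810329, 0.0386347712941647, 0.0707636873185867, 0.0227204484035632, 0.0591532379141227, 0.0580522470223201, 0.0965869282354119, 0.0241217095385847, 0.0406365729156241, 0.0474426984285857, 0.0393354018616755, 0.05534981483335, 0.0664598138324492, 0.0535481933740366, 0.0686617956160545, 0.0110099089180262, 0.029226303673306],
    "ss_pos": [0.25, 0.15, 0.6],
    "ss_neg": [0.35, 0.25, 0.4],
    "rsa_pos": {
      "means": [0.25, 0.35, 0.45],
      "sd": 0.06,
      "weights": [1, 1, 1]
    },
    "rsa_neg": {
      "means": [0.15, 0.55],
      "sd": 0.18,
      "weights": [1, 1]
    },
    "rsa_max": 0.85,
    "min_separation": 7,
    "annotate": true,
    "seed": 0
  }
}
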