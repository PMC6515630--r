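{
  "format": "chromocoil-coefficients",
  "version": 1,
  "c_log": -1.13,
  "eps_theta": 0.216530985056954,
  "table": [
    {
      "eps": 0,
      "a1": 0.0130342695307396,
      "a2": 0.00325430408730648,
      "a3": 29.569602743901,
      "a4": -0.0347813135429721
    },
    {
      "eps": 0.05,
      "a1": 0.0102368345443679,
      "a2": 0.00218396594934884,
      "a3": 31.9279037644869,
      "a4": -0.0209677604138569
    },
    {
      "eps": 0.1,
      "a1": 0.00715611832187683,
      "a2": 0.00153517313364287,
      "a3": 33.5950021663055,
      "a4": -0.0103359270025495
    },
    {
      "eps": 0.15,
      "a1": 0.00392848177084196,
      "a2": 0.001607423258886,
      "a3": 34.7339573694176,
      "a4": -0.00868040194309391
    },
    {
      "eps": 0.2,
      "a1": 0.00102148059230376,
      "a2": 0.00186423854861897,
      "a3": 36.0899725767032,
      "a4": -0.0089423721681152
    },
    {
      "eps": 0.25,
      "a1": -0.00190778910630608,
      "a2": 0.00151780199741494,
      "a3": 38.9398224487206,
      "a4": -0.00230653868211247
    },
    {
      "eps": 0.27,
      "a1": -0.0024819181014692,
      "a2": 0.00194269135628018,
      "a3": 40.014376645236,
      "a4": -0.00788403720653837
    },
    {
      "eps": 0.3,
      "a1": -0.00547640610338818,
      "a2": 0.00143990902685002,
      "a3": 41.226598048682,
      "a4": 0.000988326971188099
    },
    {
      "eps": 0.32,
      "a1": -0.00627688887735072,
      "a2": 0.00188219349315584,
      "a3": 41.5081573920466,
      "a4": -0.00487908221727557
    },
    {
      "eps": 0.35,
      "a1": -0.00734223519793155,
      "a2": 0.0022380592443625,
      "a3": 41.3972992309015,
      "a4": -0.0116506618354864
    },
    {
      "eps": 0.4,
      "a1": -0.0121542836529789,
      "a2": 0.000645589475829812,
      "a3": 47.5417339214848,
      "a4": 0.0180122035357673
    },
    {
      "eps": 0.44,
      "a1": -0.00983192714530733,
      "a2": 0.000839609488632316,
      "a3": 42.9809999792932,
      "a4": 0.00218881214511861
    },
    {
      "eps": 0.5,
      "a1": -0.0136272221396331,
      "a2": 0.000950565983461537,
      "a3": 40.9481437658959,
      "a4": 0.00128651420409413
    },
    {
      "eps": 0.55,
      "a1": -0.0209009000338536,
      "a2": 0.00113081688817684,
      "a3": 42.2419656725674,
      "a4": 0.00888328016094877
    },
    {
      "eps": 0.6,
      "a1": -0.0215564556776912,
      "a2": 0.000906568314586436,
      "a3": 50.6510746113466,
      "a4": 0.0133558419754271
    }
  ],
  "metadata": {
    "lattice": "simple cubic",
    "move_set": "pivot (20%) + end/corner/crankshaft (80%)",
    "master_seed": 20260919,
    "N_list": [16, 32, 64, 128, 256, 512],
    "n_samples": 2000,
    "share_elastic": false,
    "fits": {
      "eps0.0000": {
        "eps": 0,
        "N": [16, 32, 64, 128, 256, 512],
        "ks": [0.0330589403893202, 0.0269852058862324, 0.0186650043375977, 0.0263244826042525, 0.0387405970296508, 0.053939618872457],
        "nll": 47780.5741026561
      },
      "eps0.0500": {
        "eps": 0.05,
        "N": [16, 32, 64, 128, 256, 512],
        "ks": [0.0430353063326396, 0.0294571716879172, 0.017234585067874, 0.0216104083888718, 0.0274973004041947, 0.0576271171616414],
        "nll": 47087.1191935284
      },
      "eps0.1000": {
        "eps": 0.1,
        "N": [16, 32, 64, 128, 256, 512],
        "ks": [0.0244487753715299, 0.0272412649337209, 0.0263241883247533, 0.0246360114203057, 0.0214940764780864, 0.0654212519699607],
        "nll": 46607.969173695
      },
      "eps0.1500": {
        "eps": 0.15,
        "N": [16, 32, 64, 128, 256, 512],
        "ks": [0.0300573814173936, 0.0385729111191032, 0.0261181640871647, 0.0356545190372191, 0.0326051625908489, 0.0521025680626156],
        "nll": 46164.4793910002
      },
      "eps0.2000": {
        "eps": 0.2,
        "N": [16, 32, 64, 128, 256, 512],
        "ks": [0.0263894699589844, 0.0314051657382074, 0.0388855928589611, 0.0219508011215107, 0.0375143194335015, 0.0710847377874988],
        "nll": 45596.1377966121
      },
      "eps0.2500": {
        "eps": 0.25,
        "N": [16, 32, 64, 128, 256, 512],
        "ks": [0.0321348382246727, 0.0451334511787691, 0.0310085644752447, 0.0146778384407344, 0.0399592223566227, 0.0882969674100809],
        "nll": 44726.2989018319
      },
      "eps0.2700": {
        "eps": 0.27,
        "N": [16, 32, 64, 128, 256, 512],
        "ks": [0.0421900975480842, 0.0619735515845596, 0.0372978549905503, 0.0434767602322503, 0.0510953265363072, 0.102890321600474],
        "nll": 44181.3409345196
      },
      "eps0.3000": {
        "eps": 0.3,
        "N": [16, 32, 64, 128, 256, 512],
        "ks": [0.0468940046614185, 0.0522420628979191, 0.0339349088546077, 0.0230540078578793, 0.0488795633978265, 0.101950621796089],
        "nll": 43343.8362718015
      },
      "eps0.3200": {
        "eps": 0.32,
        "N": [16, 32, 64, 128, 256, 512],
        "ks": [0.0798731068619892, 0.0495471708336914, 0.0194610246860801, 0.0381411073611347, 0.0825976400245076, 0.102088252641934],
        "nll": 42482.5550921547
      },
      "eps0.3500": {
        "eps": 0.35,
        "N": [16, 32, 64, 128, 256, 512],
        "ks": [0.0916493591052729, 0.0465322279656738, 0.0200849459677913, 0.0340530474348957, 0.0927539390262931, 0.103386458771169],
        "nll": 40670.258560682
      },
      "eps0.4000": {
        "eps": 0.4,
        "N": [16, 32, 64, 128, 256, 512],
        "ks": [0.0769734355994693, 0.0590548348649517, 0.0543082602982088, 0.0750471536446335, 0.165621772172782, 0.0848430982724936],
        "nll": 34409.1063958081
      },
      "eps0.4400": {
        "eps": 0.44,
        "N": [16, 32, 64, 128, 256, 512],
        "ks": [0.0925304267989043, 0.0682830337512547, 0.061809729334471, 0.153620084749702, 0.0450178699308394, 0.0991112752212963],
        "nll": 33439.6246395376
      },
      "eps0.5000": {
        "eps": 0.5,
        "N": [16, 32, 64, 128, 256, 512],
        "ks": [0.062299601405245, 0.047452737847658, 0.0596835698109397, 0.0715886284845687, 0.224067774759659, 0.170519042420467],
        "nll": 27560.7556707085
      },
      "eps0.5500": {
        "eps": 0.55,
        "N": [16, 32, 64, 128, 256, 512],
        "ks": [0.0366993653304924, 0.0302004162296555, 0.0856032273874385, 0.112919394925324, 0.0285714373115304, 0.0838188554127947],
        "nll": 23350.1985292134
      },
      "eps0.6000": {
        "eps": 0.6,
        "N": [16, 32, 64, 128, 256, 512],
        "ks": [0.0742959928558484, 0.0530480806184435, 0.0692457185617762, 0.0467560109397218, 0.128606686353433, 0.104712191964539],
        "nll": 21889.3964732879
      }
    }
  }
}
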