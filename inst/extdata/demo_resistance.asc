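ncols 12
nrows 12
xllcorner 0
yllcorner 0
cellsize 1000
NODATA_value -9999
1.0035600104060518 1.0054557018740578 1.0075084728164003 1.0093156302537576 1.0104989678766649 1.0109055712638637 1.0107031235094517 1.0102784268647853 1.0099876154573608 1.0099269801759037 1.0098869030410653 1.0095164114174182
1.0099925777025518 1.0153123404191526 1.0210702263900562 1.0261323898468955 1.0294313833407167 1.0305302420094264 1.0298924899668125 1.0286020664222344 1.0276674312375556 1.0273801745511271 1.0271807967603237 1.02610938073908
1.0250986093038477 1.0384573403665753 1.0529097001220866 1.0655991350688916 1.073830150052008 1.0764862230536838 1.0747140955752013 1.0712319781896296 1.068594473443629 1.067586185808771 1.0668725480874981 1.0641043129779026
1.056411496403999 1.0864298184184744 1.1188912310160211 1.1473564096751976 1.1657354930906643 1.1714773704329648 1.1671210798253715 1.1587665271875556 1.1522028373531099 1.1493079386529044 1.1472373465933203 1.1408463860117535
1.1134570274309077 1.1738179403938689 1.2390631797668861 1.2962045472098003 1.3329321175922197 1.3440333473060182 1.3345395771824906 1.3167004854680959 1.3022523995122968 1.2951968072429352 1.2901169880195156 1.2769315357701638
1.2041930618653367 1.3128039323518002 1.4301538598917203 1.5328022187660779 1.5984859492095231 1.6176805074828069 1.5993088627460395 1.5653844276745239 1.537192800434303 1.5223297408940772 1.5115805834516627 1.4872679488104994
1.3288488621628567 1.5037283295430925 1.6926010472361899 1.857613851660906 1.9627422483380434 1.9924220179752665 1.9608158743150357 1.9033244373298432 1.8544841995286991 1.8271470642427139 1.8073118214090091 1.7672422071265963
1.4739117421025951 1.7258837577122332 1.9979081617554546 2.2352898034449833 2.3858736021475648 2.4269131569630429 2.3785269526785724 2.2916591974682827 2.2164417123187197 2.1722658524041623 2.1401331947142004 2.0811023872855516
1.6111451104499201 1.9360181625203849 2.2866073932850148 2.5921980441717767 2.7852311444390621 2.8359754719709498 2.770008404814198 2.6529352366136827 2.5498581517446581 2.4868782627777746 2.4409786406353526 2.3632369995335281
1.7052400100427227 2.0800601240681496 2.4843949754415409 2.8364382544822462 3.0578904559353588 3.1139948253701633 3.0338537740755664 2.8930709479380341 2.7672822894608009 2.687839422520236 2.6298507192771337 2.5383197163603253
1.7282412198173325 2.1152134877675368 2.532501128481444 2.8954243244826126 3.1227886084837486 3.1782524754187982 3.0914515672410321 2.9403520285165632 2.8035706003001959 2.7147220897352904 2.6497840630992666 2.5534349196465524
1.6729135415113501 2.0304204890165294 2.4157936361933752 2.7506015337431968 2.9595108729004158 3.0085345643197776 2.9246818448603649 2.7799023377906114 2.6473031167458312 2.5590632463117906 2.4945003789814648 2.4038194498552103
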